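## Connectome partner ranking: aggregate a neuPrint-style connection export
## by cell type, rank partners above a weight threshold, and export the
## node/link structure Sankey renderers consume.

#' Load a neuPrint-style synapse connection table
#'
#' Reads a delimited table with header columns \code{bodyId_pre, type_pre,
#' bodyId_post, type_post, weight} (comma- or tab-separated, auto-detected).
#' Duplicate body pairs are summed into one logical connection; missing or
#' empty types become \code{"untyped"}. Row count and total weight are
#' reported via \code{message()}.
#'
#' @param path file path.
#' @return a \linkS4class{SynapseTable}.
#' @export
loadSynapseTable <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("bodyId_pre", "type_pre", "bodyId_post", "type_post", "weight")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required columns; found: %s",
                 paste(names(df), collapse = ", ")), call. = FALSE)
  df <- df[, need]
  for (col in c("type_pre", "type_post")) {
    v <- as.character(df[[col]])
    v[is.na(v) | v == ""] <- "untyped"
    df[[col]] <- v
  }
  if (nrow(df)) {
    key <- paste(df$bodyId_pre, df$bodyId_post, sep = "\r")
    agg <- rowsum(as.numeric(df$weight), key, reorder = FALSE)
    first <- !duplicated(key)
    df <- df[first, ]
    df$weight <- as.integer(agg[match(paste(df$bodyId_pre, df$bodyId_post,
                                            sep = "\r"), rownames(agg)), 1])
    rownames(df) <- NULL
  }
  message(sprintf("loaded %d connections, total weight %d",
                  nrow(df), sum(df$weight)))
  new("SynapseTable", connections = df)
}

#' Rank synaptic partners of a cell type
#'
#' Sums connection weights of every partner type either postsynaptic
#' (\code{direction = "downstream"}) or presynaptic (\code{"upstream"}) to
#' \code{source_type}, drops partners whose total is below
#' \code{min_weight}, and sorts by descending total weight with
#' lexicographic tie-break.
#'
#' @param table a \linkS4class{SynapseTable}.
#' @param source_type focal cell type; must occur in the table.
#' @param direction "downstream" or "upstream".
#' @param min_weight inclusion threshold on the summed type-pair weight.
#' @return a \linkS4class{PartnerRanking} (dropped weight recorded for the
#'   conservation invariant retained + dropped = total incident).
#' @export
rankPartners <- function(table, source_type,
                         direction = c("downstream", "upstream"),
                         min_weight = 1) {
  direction <- match.arg(direction)
  con <- table@connections
  known <- sort(unique(c(con$type_pre, con$type_post)))
  if (!source_type %in% known)
    stop(sprintf("source type '%s' not present; known types: %s",
                 source_type, paste(known, collapse = ", ")), call. = FALSE)
  if (direction == "downstream") {
    sel <- con[con$type_pre == source_type, ]
    partner <- sel$type_post
    bodies <- sel$bodyId_post
  } else {
    sel <- con[con$type_post == source_type, ]
    partner <- sel$type_pre
    bodies <- sel$bodyId_pre
  }
  if (nrow(sel) == 0) {
    entries <- data.frame(partner_type = character(0),
                          total_weight = numeric(0),
                          n_partner_bodies = integer(0))
    return(new("PartnerRanking", source_type = source_type,
               direction = direction, entries = entries,
               min_weight = min_weight, dropped_weight = 0))
  }
  tw <- tapply(as.numeric(sel$weight), partner, sum)
  nb <- tapply(bodies, partner, function(b) length(unique(b)))
  entries <- data.frame(partner_type = names(tw),
                        total_weight = as.numeric(tw),
                        n_partner_bodies = as.integer(nb[names(tw)]),
                        stringsAsFactors = FALSE)
  keep <- entries$total_weight >= min_weight
  dropped <- sum(entries$total_weight[!keep])
  entries <- entries[keep, , drop = FALSE]
  entries <- entries[order(-entries$total_weight, entries$partner_type), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  new("PartnerRanking", source_type = source_type, direction = direction,
      entries = entries, min_weight = min_weight, dropped_weight = dropped)
}

#' Convert a partner ranking to Sankey nodes and links
#'
#' One node for the source type plus one per retained partner; each link
#' carries the summed type-pair weight. Node indices are 0-based as
#' expected by standard Sankey renderers; serialize with
#' \code{\link{sankeyJSON}}.
#'
#' @param ranking a \linkS4class{PartnerRanking}.
#' @return a \linkS4class{SankeyData}.
#' @export
toSankey <- function(ranking) {
  e <- ranking@entries
  nodes <- c(ranking@source_type, e$partner_type)
  if (nrow(e) == 0) {
    links <- data.frame(source = integer(0), target = integer(0),
                        value = numeric(0))
  } else if (ranking@direction == "downstream") {
    links <- data.frame(source = 0L, target = seq_len(nrow(e)),
                        value = e$total_weight)
  } else {
    links <- data.frame(source = seq_len(nrow(e)), target = 0L,
                        value = e$total_weight)
  }
  new("SankeyData", nodes = nodes, links = links)
}

#' Serialize SankeyData to JSON
#'
#' @param sankey a \linkS4class{SankeyData}.
#' @param path optional output file; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
sankeyJSON <- function(sankey, path = NULL) {
  obj <- list(nodes = lapply(sankey@nodes, function(l) list(label = l)),
              links = list(source = sankey@links$source,
                           target = sankey@links$target,
                           value = sankey@links$value))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
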