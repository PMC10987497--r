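## Synthetic synapse-table fixture generator: plants exact type-pair weights
## recoverable by aggregation.

#' Generate a synthetic synapse table with planted type-pair weights
#'
#' Each planted (pre type, post type, weight) entry is split across a random
#' number of distinct body pairs whose integer weights sum exactly to the
#' planted value; all body ids are unique within a type, so aggregating the
#' table by type pair recovers the planted map exactly.
#'
#' @param config a \linkS4class{SynthConfig} (supplies the seed).
#' @param planted data.frame(type_pre, type_post, weight) of planted summed
#'   weights (positive integers); may be empty.
#' @return a \linkS4class{SynapseTable}.
#' @examples
#' tab <- genSynapseTable(synthConfig(1), data.frame(
#'   type_pre = "DN1a", type_post = c("DN3", "LNd", "KC(a'b')"),
#'   weight = c(50, 30, 10)))
#' @export
genSynapseTable <- function(config, planted) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(new("SynapseTable", connections = data.frame(
      bodyId_pre = integer(0), type_pre = character(0),
      bodyId_post = integer(0), type_post = character(0),
      weight = integer(0))))
  }
  stopIfNot(all(planted$weight >= 1), "planted weights must be >= 1")
  withSubstream(config@master_seed, 800000L, {
    next_body <- 1000L
    body_of <- new.env(parent = emptyenv())
    bodiesFor <- function(type, k) {
      have <- if (!is.null(body_of[[type]])) body_of[[type]] else integer(0)
      while (length(have) < k) {
        next_body <<- next_body + sample.int(17L, 1L)
        have <- c(have, next_body)
      }
      body_of[[type]] <- have
      have
    }
    rows <- lapply(seq_len(nrow(planted)), function(i) {
      w <- as.integer(planted$weight[i])
      n_pairs <- sample.int(min(4L, w), 1L)
      # random positive integer composition of w into n_pairs parts
      if (n_pairs == 1L) parts <- w
      else {
        cuts <- sort(sample.int(w - 1L, n_pairs - 1L))
        parts <- diff(c(0L, cuts, w))
      }
      pre_b <- bodiesFor(planted$type_pre[i], n_pairs)[seq_len(n_pairs)]
      post_b <- bodiesFor(paste0("post_", planted$type_post[i]), n_pairs)[seq_len(n_pairs)]
      data.frame(bodyId_pre = pre_b, type_pre = planted$type_pre[i],
                 bodyId_post = post_b, type_post = planted$type_post[i],
                 weight = as.integer(parts))
    })
    new("SynapseTable", connections = do.call(rbind, rows))
  })
}
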