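## Group comparison: one-way ANOVA with Tukey HSD post test and a compact
## letter display, falling back to a two-tailed t test for two groups.

#' Compact letter display by insert-and-absorb
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if their pairwise comparison is non-significant. Starts from one letter
#' covering all groups; each significant pair splits every letter set
#' containing both; sets contained in other sets are absorbed.
#'
#' @param pmat symmetric matrix of pairwise p-values with group names on
#'   both dimensions (diagonal ignored).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
compactLetters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  sets <- list(groups)
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- groups[pairs[k, 1]]; j <- groups[pairs[k, 2]]
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # drop empties and duplicates, absorb sets contained in another set
    new_sets <- new_sets[vapply(new_sets, length, 0L) > 0]
    new_sets <- unique(lapply(new_sets, function(s) s[order(match(s, groups))]))
    keep <- vapply(seq_along(new_sets), function(x)
      !any(vapply(seq_along(new_sets), function(y)
        y != x && all(new_sets[[x]] %in% new_sets[[y]]), TRUE)), TRUE)
    sets <- new_sets[keep]
  }
  # stable order: sets sorted by first member's group position
  first_pos <- vapply(sets, function(s) min(match(s, groups)), 0L)
  sets <- sets[order(first_pos)]
  letters_used <- make.unique(rep(LETTERS, length.out = length(sets)))
  out <- setNames(rep("", length(groups)), groups)
  for (si in seq_along(sets))
    for (g in sets[[si]])
      out[g] <- paste0(out[g], letters_used[si])
  out
}

#' Group statistics: ANOVA, Tukey post test and letters
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference post
#' test, with a compact letter display in which groups not significantly
#' different share a letter. With exactly two groups a two-tailed t test is
#' used instead. When every group has zero within-group variance the test
#' is skipped with a message (exact ties carry no usable error term) and
#' letters are assigned by exact equality of the group means.
#'
#' @param values numeric vector of per-fly values.
#' @param groups group labels, same length.
#' @param alpha significance level for the letters (default 0.05).
#' @return list: \code{method}, \code{anova} (or t-test), \code{tukey}
#'   (data.frame of pairwise comparisons), \code{p_matrix},
#'   \code{letters}, \code{group_means}.
#' @export
groupStats <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopIfNot(nlevels(groups) >= 2, "need >= 2 groups")
  sizes <- table(groups)
  stopIfNot(all(sizes >= 2), "each group needs n >= 2")
  lev <- levels(groups)
  stopIfNot(!any(grepl("-", lev, fixed = TRUE)),
            "group labels must not contain '-' (Tukey comparison parsing)")
  gmeans <- tapply(values, groups, mean)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    message("all groups have zero within-group variance; test skipped, ",
            "letters assigned by exact equality of group means")
    pm <- outer(gmeans, gmeans, function(a, b) as.numeric(a == b))
    dimnames(pm) <- list(lev, lev)
    return(list(method = "degenerate (zero variance)", anova = NULL,
                tukey = NULL, p_matrix = pm,
                letters = compactLetters(pm, alpha), group_means = gmeans))
  }
  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups)
    pm <- matrix(tt$p.value, 2, 2, dimnames = list(lev, lev))
    diag(pm) <- 1
    return(list(method = "two-tailed t test", anova = tt,
                tukey = NULL, p_matrix = pm,
                letters = compactLetters(pm, alpha), group_means = gmeans))
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pm <- matrix(1, nlevels(groups), nlevels(groups),
               dimnames = list(lev, lev))
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_len(nrow(tk))) {
    a <- cmp[[r]][1]; b <- cmp[[r]][2]
    pm[a, b] <- pm[b, a] <- tk[r, "p adj"]
  }
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(method = "one-way ANOVA + Tukey HSD", anova = summary(fit),
       tukey = tukey, p_matrix = pm, letters = compactLetters(pm, alpha),
       group_means = gmeans)
}
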