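# Group-comparison statistics used for missingness-by-species analyses:
# Levene's test (equality of variances), Welch's ANOVA (unequal variances)
# and the Games-Howell post hoc with a compact letter display.

.check_groups <- function(values, groups, min_n = 2L) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) .stopf("need >= 2 groups")
  n <- tapply(values, g, length)
  if (any(n < min_n)) .stopf("every group needs >= %d observations", min_n)
  g
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center (mean by
#' default, matching the classical form of the test).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param center \code{"mean"} or \code{"median"} (Brown-Forsythe).
#' @return list: \code{W} (the F statistic on deviations), \code{df1},
#'   \code{df2}, \code{p}.
#' @export
leveneVarTest <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- .check_groups(values, groups)
  fit <- car::leveneTest(values, g,
                         center = if (center == "mean") mean else median)
  list(W = fit[1, "F value"], df1 = fit[1, "Df"], df2 = fit[2, "Df"],
       p = fit[1, "Pr(>F)"])
}

#' Welch's ANOVA (unequal variances)
#'
#' One-way comparison of group means without assuming equal variances,
#' via \code{\link[stats]{oneway.test}} with \code{var.equal = FALSE}
#' (Welch 1951 weights n_i / s_i^2).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, each n >= 2, each variance
#'   > 0).
#' @return list: \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
welchAnova <- function(values, groups) {
  g <- .check_groups(values, groups)
  v <- tapply(values, g, stats::var)
  if (any(v == 0)) .stopf("zero within-group variance")
  ft <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Games-Howell post hoc test with compact letter display
#'
#' All pairwise comparisons of group means under unequal variances:
#' t = |mean_i - mean_j| / sqrt(s_i^2/n_i + s_j^2/n_j) with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution with q = t * sqrt(2) and k groups. At k = 2 this is
#' exactly the Welch two-sample t-test. Letters are assigned by the
#' insert-and-absorb algorithm over the non-significance graph: groups
#' sharing a letter do not differ at \code{alpha}.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list: \code{pairs} (data.frame \code{group_i, group_j, diff, se,
#'   df, p}), \code{letters} (named character vector).
#' @export
gamesHowell <- function(values, groups, alpha = 0.05) {
  g <- .check_groups(values, groups)
  v <- tapply(values, g, stats::var)
  if (any(v == 0)) .stopf("zero within-group variance")
  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  k <- nlevels(g)
  lev <- levels(g)
  cmb <- utils::combn(k, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(c2) {
    i <- cmb[1, c2]; j <- cmb[2, c2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    t <- abs(m[i] - m[j]) / sqrt(se2)
    data.frame(group_i = lev[i], group_j = lev[j],
               diff = unname(m[i] - m[j]), se = sqrt(se2),
               df = unname(df),
               p = stats::ptukey(t * sqrt(2), k, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(pairs = pairs,
       letters = .compact_letters(lev[order(m)], pairs, alpha))
}

# Insert-and-absorb compact letter display. `order` lists groups (by mean);
# `pairs` has group_i/group_j/p. Groups sharing a letter are not
# significantly different.
.compact_letters <- function(order_groups, pairs, alpha) {
  sets <- list(order_groups)
  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    gi <- sig$group_i[r]; gj <- sig$group_j[r]
    new_sets <- list()
    for (s in sets) {
      if (all(c(gi, gj) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets))
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(a < b && identical(new_sets[[a]], new_sets[[b]])))
        if (length(new_sets[[a]]) < length(new_sets[[b]]) ||
            (identical(new_sets[[a]], new_sets[[b]]) && a > b))
          keep[a] <- FALSE
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # stable ordering: by first member's position in the mean ordering
  first_pos <- vapply(sets, function(s)
    min(match(s, order_groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", length(order_groups)), order_groups)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}
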