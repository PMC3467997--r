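# ANOVA relative-importance (RIM) sensitivity screening, 1-5 rank scaling,
# per-ligament aggregation and laxity-test selection.

#' Relative importance of one design factor
#'
#' Main-effect ANOVA ratio on a balanced three-level column: with m the grand
#' mean of the n responses and m_Aj the mean of the n/3 responses at level j,
#' \deqn{SS_A = \frac{n}{3}\sum_{j=1}^{3} (m_{Aj} - m)^2, \qquad
#'       TSS = \sum_i (\eta_i - m)^2, \qquad RIM_A = SS_A / TSS.}
#' For the L81 array n/3 = 27, the number of times each level repeats.
#'
#' @param levels integer vector of factor levels (1, 2, 3), one per design row
#' @param response laxity magnitudes, same length
#' @return RIM value in [0, 1]
#' @export
rim <- function(levels, response) {
  n <- length(response)
  if (length(levels) != n) stop("levels and response lengths differ")
  cnt <- tabulate(levels, 3)
  if (!all(cnt == n / 3))
    stop("factor column is not balanced: level counts ",
         paste(cnt, collapse = "/"))
  m <- mean(response)
  tss <- sum((response - m)^2)
  if (tss <= n * 1e-24)
    stop("degenerate response: total sum of squares is zero, RIM undefined")
  mj <- vapply(1:3, function(j) mean(response[levels == j]), 0)
  ss <- (n / 3) * sum((mj - m)^2)
  ss / tss
}

#' RIM matrix for all factors and all laxity tests
#'
#' @param design L81 array (or its realized subset; columns must be balanced)
#' @param responses matrix of laxity magnitudes, one row per design row and
#'   one column per laxity test (e.g. `AP-00` ... `VV-120`)
#' @return factors x tests matrix of RIM values
#' @export
rim_table <- function(design, responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) != nrow(design))
    stop("responses must have one row per design row")
  out <- matrix(NA_real_, ncol(design), ncol(responses),
                dimnames = list(colnames(design), colnames(responses)))
  for (j in seq_len(ncol(responses)))
    for (i in seq_len(ncol(design)))
      out[i, j] <- rim(design[, i], responses[, j])
  out
}

#' Scale a row of RIM values to 1-5 ranks
#'
#' Linear rescaling within one factor row across the laxity tests:
#' rank = 1 + round(4 (RIM - min) / (max - min)), rounding half-up, so the
#' maximum-RIM test gets rank 5 and the minimum rank 1. A constant row is
#' undefined; it is assigned the midpoint rank 3 with a warning.
#'
#' @param x numeric vector of RIM values (one factor, all tests)
#' @return integer ranks in 1..5
#' @export
rank_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) {
    warning("all RIM values equal; assigning midpoint rank 3")
    return(rep(3L, length(x)))
  }
  as.integer(1 + round_half_up(4 * (x - rng[1]) / diff(rng)))
}

#' Rank matrix (1-5) from a RIM matrix
#'
#' @param rim_mat factors x tests RIM matrix
#' @return integer matrix of the same shape
#' @export
rank_table <- function(rim_mat) {
  out <- t(apply(rim_mat, 1, rank_scale))
  dimnames(out) <- dimnames(rim_mat)
  storage.mode(out) <- "integer"
  out
}

# strain-factor rows of a 40-factor matrix, named by ligament.region
strain_factor_rows <- function(mat, factors) {
  idx <- which(factors$kind == "eps")
  out <- mat[idx, , drop = FALSE]
  rownames(out) <- paste(factors$ligament[idx],
                         substr(factors$region[idx], 1, 1), sep = "-")
  out
}

#' Per-ligament mean ranks across laxity tests
#'
#' Averages the 1-5 ranks of each ligament's strain factors (bundle-region
#' groups) for every laxity test.
#'
#' @param ranks strain-factor rank matrix (14 x tests), rownames like
#'   `ACL-a`
#' @return ligament x tests matrix of mean ranks
#' @export
ligament_rank_table <- function(ranks) {
  lig <- sub("-.*$", "", rownames(ranks))
  ligs <- unique(lig)
  out <- t(vapply(ligs, function(lg)
    colMeans(ranks[lig == lg, , drop = FALSE]), numeric(ncol(ranks))))
  dimnames(out) <- list(ligs, colnames(ranks))
  out
}

#' Select the laxity tests to use intraoperatively
#'
#' A test is selected when any ligament's mean rank for it reaches the
#' threshold (default 3 on the 1-5 scale).
#'
#' @param ranks strain-factor rank matrix (14 x tests)
#' @param threshold selection cutoff on the per-ligament mean rank
#' @return list with `selected` (test ids, in column order), `ligament_means`
#'   (ligament x tests matrix) and `attribution` (per selected test, the
#'   ligaments meeting the threshold)
#' @export
select_tests <- function(ranks, threshold = 3) {
  lm <- ligament_rank_table(ranks)
  hit <- lm >= threshold
  selected <- colnames(lm)[colSums(hit) > 0]
  attribution <- lapply(selected, function(ts) rownames(lm)[hit[, ts]])
  names(attribution) <- selected
  list(selected = selected, ligament_means = lm, attribution = attribution)
}

#' Assemble the full sensitivity table
#'
#' RIM values for all 40 factors, 1-5 ranks, the strain-factor (bundle
#' region) sub-table, per-ligament mean ranks and the selected laxity tests.
#' Attachment and stiffness factor RIMs are retained as nuisance-sensitivity
#' output.
#'
#' @param design L81 array
#' @param responses rows x tests laxity matrix
#' @param factors factor table from [design_factors()]
#' @param threshold selection cutoff
#' @return object of class `sensitivity_table`
#' @export
sensitivity_table <- function(design, responses, factors = design_factors(),
                              threshold = 3) {
  rim_all <- rim_table(design, responses)
  ranks_all <- rank_table(rim_all)
  rim_strain <- strain_factor_rows(rim_all, factors)
  ranks_strain <- strain_factor_rows(ranks_all, factors)
  sel <- select_tests(ranks_strain, threshold)
  structure(list(rim = rim_all, ranks = ranks_all,
                 rim_strain = rim_strain, ranks_strain = ranks_strain,
                 ligament_means = sel$ligament_means,
                 selected = sel$selected, attribution = sel$attribution,
                 threshold = threshold, factors = factors),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("sensitivity map (strain factors x laxity tests), ranks 1-5:\n")
  print(x$ranks_strain)
  cat("\nselected laxity tests (ligament mean rank >=", x$threshold, "):",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Factor-effect plot for one laxity test
#'
#' Level means of the response for each factor (analogous to a main-effects
#' screening plot), with the grand mean as a dashed line.
#'
#' @param design L81 array
#' @param response laxity magnitudes, one per row
#' @param factors factor table (for labels); NULL for bare column names
#' @param ... passed to [graphics::matplot()]
#' @export
plot_factor_effects <- function(design, response, factors = NULL, ...) {
  mj <- sapply(seq_len(ncol(design)), function(i)
    vapply(1:3, function(j) mean(response[design[, i] == j]), 0))
  graphics::matplot(t(mj), type = "p", pch = c(1, 3, 2),
                    xlab = "parameter", ylab = "level-mean laxity", ...)
  graphics::abline(h = mean(response), lty = 2)
  invisible(t(mj))
}
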