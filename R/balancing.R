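# Ordered intraoperative soft-tissue balancing plan derived from the
# sensitivity map.

#' Derive the soft-tissue balancing sequence
#'
#' Greedy sequencing over the selected laxity tests: at each step, among the
#' selected tests not yet used, pick the one whose high-sensitivity bundle
#' groups (rank >= `threshold`) contain the fewest still-unadjusted groups
#' (at least one); ties are broken by earlier flexion angle, then by test
#' direction AP < IE < VV. The step adjusts exactly those unadjusted groups.
#' Starting from the laxity components sensitive to few bundles gradually
#' reduces the number of unadjusted ligaments confounding the later,
#' broadly sensitive tests.
#'
#' @param ranks strain-factor rank matrix (14 bundle-region groups x tests)
#' @param selected selected test ids (see [select_tests()]); defaults to all
#'   columns of `ranks`
#' @param threshold rank defining "high sensitivity" (default 3)
#' @return object of class `balancing_plan`: ordered steps, each with the
#'   laxity test, the groups adjusted at that step, and the groups still
#'   unadjusted before it
#' @export
derive_sequence <- function(ranks, selected = colnames(ranks), threshold = 3) {
  if (!length(selected)) stop("no laxity tests selected")
  high <- ranks[, selected, drop = FALSE] >= threshold
  groups <- rownames(ranks)
  uncov <- groups[rowSums(high) == 0]
  if (length(uncov))
    stop("bundle groups with no high-rank selected test (uncoverable): ",
         paste(uncov, collapse = ", "))
  test_dir <- sub("-.*$", "", selected)
  test_angle <- as.numeric(sub("^.*-", "", selected))
  dir_order <- match(test_dir, c("AP", "IE", "VV"))

  unadjusted <- groups
  available <- selected
  steps <- list()
  while (length(unadjusted)) {
    n_unadj <- vapply(available, function(ts)
      sum(high[unadjusted, ts, drop = TRUE]) + 0, 0)
    cand <- available[n_unadj >= 1]
    if (!length(cand))
      stop("remaining groups not coverable by unused selected tests: ",
           paste(unadjusted, collapse = ", "))
    ord <- order(n_unadj[cand], test_angle[match(cand, selected)],
                 dir_order[match(cand, selected)])
    pick <- cand[ord[1]]
    adjust <- unadjusted[high[unadjusted, pick]]
    steps[[length(steps) + 1L]] <- list(
      test = pick, adjust = adjust, unadjusted_before = unadjusted)
    unadjusted <- setdiff(unadjusted, adjust)
    available <- setdiff(available, pick)
  }
  structure(list(steps = steps, groups = groups, threshold = threshold),
            class = "balancing_plan")
}

#' Balancing plan as a step x group table
#'
#' `"X"` marks the bundle groups adjusted at a step, `"*"` the groups not yet
#' adjusted when the step is reached, and `""` groups already handled.
#'
#' @param plan a `balancing_plan`
#' @return data.frame (one row per step, columns `test` + one per group)
#' @export
plan_table <- function(plan) {
  out <- data.frame(step = seq_along(plan$steps),
                    test = vapply(plan$steps, `[[`, "", "test"),
                    stringsAsFactors = FALSE)
  for (g in plan$groups) {
    out[[g]] <- vapply(plan$steps, function(s) {
      if (g %in% s$adjust) "X"
      else if (g %in% s$unadjusted_before) "*"
      else ""
    }, "")
  }
  out
}

#' @export
print.balancing_plan <- function(x, ...) {
  cat("soft-tissue balancing sequence (", length(x$steps), " steps):\n",
      sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %d. %s: adjust %s\n", i, s$test,
                paste(s$adjust, collapse = ", ")))
  }
  invisible(x)
}
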