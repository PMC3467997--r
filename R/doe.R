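# Taguchi L81(3^40) orthogonal array and the factor -> model-parameter map.

#' Build the L81(3^40) orthogonal array
#'
#' Rao-Hamming construction over GF(3): rows are indexed by the 81 vectors
#' r of GF(3)^4 (lexicographic), columns by the 40 canonical representatives
#' c of the distinct one-dimensional directions of GF(3)^4 (first nonzero
#' coordinate 1, lexicographic); the entry is (r . c mod 3) + 1. Every level
#' appears exactly 27 times in each column and every ordered pair of columns
#' contains each of the 9 level combinations exactly 9 times.
#'
#' @return 81 x 40 integer matrix with entries in {1, 2, 3}, columns named
#'   `P01` ... `P40`
#' @export
build_L81 <- function() {
  base3 <- function(i, n) {
    d <- integer(n)
    for (j in n:1) { d[j] <- i %% 3L; i <- i %/% 3L }
    d
  }
  rows <- t(vapply(0:80, base3, integer(4), n = 4L))
  dirs <- t(vapply(1:80, base3, integer(4), n = 4L))
  first_nz <- apply(dirs, 1, function(v) v[which(v != 0)[1]])
  dirs <- dirs[first_nz == 1L, , drop = FALSE]   # canonical representatives
  stopifnot(nrow(dirs) == 40)
  A <- (rows %*% t(dirs)) %% 3L + 1L
  storage.mode(A) <- "integer"
  colnames(A) <- sprintf("P%02d", 1:40)
  A
}

#' The 40-factor definition table
#'
#' Maps each design factor to its model parameter and three levels:
#' factors 1-20 are attachment-coordinate deviations (TX, TY on the tibia;
#' FX, FY on the femur; blocks ACL, PCL, sMCL, LCL, and one shared block for
#' dMCL+PMC), factors 21-26 the six group stiffnesses, factors 27-40 the 14
#' region reference strains. Attachment levels are nominal + {-1, 0, +1} mm,
#' stiffness levels nominal x {0.95, 1, 1.05}, strain levels nominal +
#' {-s, 0, +s} with `s = config$doe$strain_step`.
#'
#' @param config configuration list
#' @return data.frame with columns index, ligament, kind, region,
#'   level1, level2, level3
#' @export
design_factors <- function(config = default_config()) {
  doe <- config$doe
  gl <- config$ligaments$groups
  rows <- list()
  add <- function(ligament, kind, region, l1, l2, l3) {
    rows[[length(rows) + 1L]] <<- data.frame(
      index = length(rows) + 1L, ligament = ligament, kind = kind,
      region = region, level1 = l1, level2 = l2, level3 = l3,
      stringsAsFactors = FALSE)
  }
  s <- doe$attachment_step_mm
  for (lig in c("ACL", "PCL", "sMCL", "LCL", "dMCL+PMC"))
    for (kind in c("TX", "TY", "FX", "FY"))
      add(lig, kind, "", -s, 0, s)
  for (lig in c("ACL", "PCL", "sMCL", "dMCL", "LCL", "PMC")) {
    k <- gl[[lig]]$k
    add(lig, "K", "", k * (1 - doe$stiffness_frac), k,
        k * (1 + doe$stiffness_frac))
  }
  for (lig in c("ACL", "PCL", "sMCL", "dMCL", "LCL", "PMC"))
    for (reg in names(gl[[lig]]$regions)) {
      e <- gl[[lig]]$regions[[reg]]$eps
      add(lig, "eps", reg, e - doe$strain_step, e, e + doe$strain_step)
    }
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 40)
  out
}

factor_level_value <- function(factors, index, level) {
  factors[index, c("level1", "level2", "level3")][[level]]
}

#' Realize one design row as a perturbed knee model
#'
#' Applies, in factor order, the attachment offsets (strain-preserving, via
#' the attachment frames; the dMCL+PMC block moves both ligaments), the
#' stiffness scalings (group stiffness re-split equally among bundles) and
#' the reference-strain replacements, all relative to the model's stored
#' nominal values. Pure: the input model is untouched and the same row always
#' produces an identical model.
#'
#' @param model nominal `knee_model` from [build_default_knee()]
#' @param row integer vector of 40 levels in {1, 2, 3}
#' @param factors factor table from [design_factors()] (defaults to the
#'   model's configuration)
#' @return perturbed `knee_model`
#' @export
realize_row <- function(model, row, factors = design_factors(model$config)) {
  if (length(row) != 40) stop("design row must have 40 levels")
  if (!all(row %in% 1:3)) stop("levels must be in {1, 2, 3}")
  model$offsets <- model$nominal$offsets
  model$group_k <- model$nominal$group_k
  model$eps <- model$nominal$eps
  for (i in 1:40) {
    f <- factors[i, ]
    val <- factor_level_value(factors, i, row[i])
    ligs <- if (f$ligament == "dMCL+PMC") c("dMCL", "PMC") else f$ligament
    if (f$kind %in% c("TX", "TY", "FX", "FY")) {
      for (lig in ligs) model$offsets[[lig]][[f$kind]] <-
          model$offsets[[lig]][[f$kind]] + val
    } else if (f$kind == "K") {
      model$group_k[[f$ligament]] <- val
    } else {
      model$eps[[paste(f$ligament, f$region, sep = ".")]] <- val
    }
  }
  refresh_model(model)
}

#' Campaign manifest: one job per (row, test, flexion)
#'
#' @param design L81 array from [build_L81()] (or a subset of its rows)
#' @param types laxity tests
#' @param flexions flexion angles, degrees
#' @return data.frame of jobs; 81 rows x 3 tests x 5 angles = 1215 for the
#'   full design
#' @export
campaign_manifest <- function(design, types = c("AP", "IE", "VV"),
                              flexions = c(0, 30, 60, 90, 120)) {
  jobs <- expand.grid(flexion = flexions, test = types, row = seq_len(nrow(design)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs <- jobs[, c("row", "test", "flexion")]
  jobs$id <- sprintf("r%02d-%s-%02d", jobs$row, jobs$test, jobs$flexion)
  rownames(jobs) <- NULL
  jobs
}

#' Write the design matrix and factor table as CSV
#'
#' @param design L81 array
#' @param factors factor table
#' @param dir output directory
#' @return invisibly, the file paths
#' @export
write_design <- function(design, factors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "design_matrix.csv")
  p2 <- file.path(dir, "design_factors.csv")
  utils::write.csv(as.data.frame(design), p1, row.names = FALSE)
  utils::write.csv(factors, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
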