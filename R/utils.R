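# small internal helpers shared across modules

vec3 <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3)
  x
}

vnorm <- function(x) sqrt(sum(x * x))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# half-up rounding (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursive list merge: values in `override` win, lists merge by name
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
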