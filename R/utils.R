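#' Round half away from zero to the nearest integer
#'
#' Commercial rounding as used for the bp/SNP summary statistic: 107.875
#' rounds to 108, 80.9 to 81, 0.5 to 1 (unlike [round()], which rounds half
#' to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Derive a reproducible sub-seed from a top-level seed and a tag
#'
#' All randomness in the package flows from a single top-level seed; each
#' stage (locus, haplotypes, clone library, bootstrap, ...) draws from its
#' own stream so that simulating one library does not perturb another.
#' The hash is kept below 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param ... character/numeric tags identifying the stage.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# sample() from the elements of x even when x has length 1
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# string <-> character-vector helpers
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste0(x, collapse = "")

# Substitute positions `pos` of a base vector with uniformly drawn different
# bases; returns the modified vector.
mutate_bases <- function(bases, pos) {
  for (p in pos) {
    bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  }
  bases
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
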