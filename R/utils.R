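# Internal helpers shared across the pipeline.

# Maximum representable intensity: images are carried as integers on the
# unsigned 16-bit scale throughout the pipeline.
UINT16_MAX <- 65535

ebtbr_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ebtbr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ebtbr_log <- function(...) {
  if (isTRUE(getOption("ebtbr.verbose", FALSE))) message(...)
}

#' Dice overlap coefficient between two binary masks
#'
#' 2|A n B| / (|A| + |B|), the standard overlap score used to compare a
#' segmentation against a ground-truth mask. 1 means identical masks.
#'
#' @param a,b binary matrices (0/1 or logical) of identical dimensions.
#' @return numeric scalar in \[0, 1\]; NaN if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_binary(a)
  b <- as_binary(b)
  if (!identical(dim(a), dim(b)))
    ebtbr_error("masks have different dimensions", "ebtbr_congruence_error")
  2 * sum(a & b) / (sum(a) + sum(b))
}

as_binary <- function(x) {
  if (inherits(x, "brain_mask")) x <- x$pixels
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  x > 0.5
}

# x[r, c] replaced by the value at (r + dr, c + dc), replicate-padded at the
# borders. Used for finite differences and non-maximum suppression.
shift_mat <- function(x, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(x)) + dr, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x)) + dc, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
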