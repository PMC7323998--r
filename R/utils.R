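# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.norm2 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm2(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Integer rounding used for reported percentages, so that e.g. 87.5 rounds
#' to 88 regardless of IEEE round-to-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# hours <-> frame helpers operate on the frame grid stored in a ground truth
.hpf_to_frame <- function(t_hpf, t_grid) {
  if (t_hpf < min(t_grid) - 1e-9 || t_hpf > max(t_grid) + 1e-9)
    .stopf("time %.3f hpf outside simulated window [%.3f, %.3f]",
           t_hpf, min(t_grid), max(t_grid))
  which.min(abs(t_grid - t_hpf))
}
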