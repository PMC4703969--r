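# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# All permutations of 1:n (n <= 9 guarded); used for exact label alignment.
permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Align estimated subpopulations to reference subpopulations
#'
#' Column order of an unsupervised deconvolution is arbitrary. This helper
#' finds, by exact enumeration over all permutations (K <= 9), the column
#' permutation of the estimate that best matches the reference, either by
#' summed Pearson correlation of mixing-matrix columns or by total marker
#' set overlap.
#'
#' @param est estimated mixing matrix (samples x K) or list of marker sets.
#' @param ref reference of the same kind as `est`.
#' @param by `"correlation"` (matrices) or `"overlap"` (marker set lists).
#' @return integer vector `perm` such that `est[, perm]` (or `est[perm]`)
#'   aligns with the reference columns/sets.
#' @export
align_subpopulations <- function(est, ref, by = c("correlation", "overlap")) {
  by <- match.arg(by)
  if (by == "correlation") {
    stopifnot(is.matrix(est), is.matrix(ref), ncol(est) == ncol(ref))
    K <- ncol(est)
    score <- cor(est, ref)  # score[i, j]: est col i vs ref col j
    score[!is.finite(score)] <- -1
  } else {
    stopifnot(is.list(est), is.list(ref), length(est) == length(ref))
    K <- length(est)
    score <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      score[i, j] <- length(intersect(est[[i]], ref[[j]]))
  }
  perms <- permutations(K)
  tot <- apply(perms, 1L, function(p) sum(score[cbind(p, seq_len(K))]))
  as.integer(perms[which.max(tot), ])
}

fmt_num <- function(x) sprintf("%.12g", x)

stage_log <- function(verbose, stage, t0, ...) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  info <- paste(vapply(list(...), as.character, ""), collapse = " ")
  message(sprintf("[camix] %-12s %6.2fs %s", stage,
                  proc.time()[[3]] - t0, info))
}
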