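#' Two-shell diffusion acquisition scheme
#'
#' Container for per-volume b-values and unit gradient directions, FSL style.
#' Shells are identified by clustering b-values within +/- 50 s/mm^2; volumes
#' with b below 50 s/mm^2 count as b = 0.
#'
#' @param bvals Numeric vector of b-values, s/mm^2, one per volume.
#' @param bvecs Numeric matrix, `length(bvals)` x 3, gradient directions.
#'   Rows for b > 0 volumes must have unit norm; b = 0 rows may be zero.
#' @return An object of class `diffusion_scheme` with fields `bvals`,
#'   `bvecs`, `b0` (logical index), `shells` (sorted unique shell b-values).
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3) {
    stop("bvecs must be n x 3 with one row per b-value", call. = FALSE)
  }
  dimnames(bvecs) <- NULL
  b0 <- bvals < 50
  if (!any(b0)) stop("scheme needs at least one b = 0 volume", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6)) {
    stop("gradient directions for b > 0 volumes must be unit vectors",
         call. = FALSE)
  }
  # cluster the b > 0 values into shells (+/- 50 s/mm^2)
  bs <- sort(unique(round(bvals[!b0] / 100) * 100))
  shells <- bs[c(TRUE, diff(bs) > 50)]
  structure(
    list(bvals = bvals, bvecs = bvecs, b0 = b0, shells = shells),
    class = "diffusion_scheme"
  )
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  cat(sprintf("diffusion scheme: %d volumes (%d b=0), shells: %s s/mm^2\n",
              length(x$bvals), sum(x$b0),
              paste(x$shells, collapse = ", ")))
  invisible(x)
}

#' Default two-shell scheme: 1 b=0 + 20 directions each at b=1000 and 2000
#'
#' Directions are a deterministic Fibonacci-spiral point set on the upper
#' hemisphere, a standard near-uniform design for diffusion sampling.
#'
#' @param n_dir Directions per shell.
#' @param shells Shell b-values, s/mm^2.
#' @return A [diffusion_scheme()].
#' @export
default_scheme <- function(n_dir = 20, shells = c(1000, 2000)) {
  dirs <- fibonacci_hemisphere(n_dir)
  bvals <- c(0, rep(shells, each = n_dir))
  bvecs <- rbind(c(0, 0, 0), do.call(rbind, rep(list(dirs), length(shells))))
  diffusion_scheme(bvals, bvecs)
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Write / read FSL-style bval and bvec files
#'
#' `bval` is one whitespace-separated row; `bvec` is three rows (x, y, z).
#'
#' @param scheme A [diffusion_scheme()].
#' @param bval_path,bvec_path Output file paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "), bvec_path)
  invisible(NULL)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvec_path), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  diffusion_scheme(bvals, t(bv))
}
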