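#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd cor fft convolve qnorm pt dgamma setNames
#' @importFrom utils head tail
#' @importFrom Matrix Matrix Diagonal sparseMatrix
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("fmripeb_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## Pearson correlation that returns NA (not an error/warning) for
## zero-variance inputs.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

## All permutations of 1..n as a matrix with one permutation per row.
## Intended for small n (matching oracles, template orderings).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

## Deterministic sub-seed derived from a base seed and a stream index,
## kept below 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) + 10007L * as.integer(k)) %% 2147483587L
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## Frobenius norm squared
fnorm2 <- function(x) sum(x^2)
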