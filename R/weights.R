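#' Spatial weight matrix for synthetic panels
#'
#' Builds a symmetric 0/1 adjacency of the requested topology and
#' row-normalizes it (rows of isolates stay zero). Synthetic estimator
#' studies use stylized topologies rather than real prefecture contiguity.
#'
#' @param kind `"ring"` (each unit borders its two cyclic neighbours),
#'   `"lattice"` (rook adjacency on a near-square grid), or `"custom"`.
#' @param n Number of units (`>= 2`).
#' @param adjacency For `kind = "custom"`: a symmetric nonnegative matrix
#'   with zero diagonal.
#' @param normalize Row-normalize the adjacency (default `TRUE`).
#' @return An `n x n` matrix with attribute `"normalized"`.
#' @examples
#' make_weight_matrix("ring", 4)
#' @export
make_weight_matrix <- function(kind = c("ring", "lattice", "custom"), n,
                               adjacency = NULL, normalize = TRUE) {
  kind <- match.arg(kind)
  if (kind != "custom") stopifnot(n >= 2)
  A <- switch(kind,
    ring = {
      A <- matrix(0, n, n)
      idx <- seq_len(n)
      A[cbind(idx, idx %% n + 1)] <- 1
      A[cbind(idx %% n + 1, idx)] <- 1
      A
    },
    lattice = {
      nr <- max(1, floor(sqrt(n)))
      nc <- ceiling(n / nr)
      A <- matrix(0, n, n)
      for (i in seq_len(n)) {
        r <- (i - 1) %/% nc
        cc <- (i - 1) %% nc
        for (d in list(c(0, 1), c(1, 0))) {
          j <- (r + d[1]) * nc + (cc + d[2]) + 1
          if (cc + d[2] < nc && j <= n) {
            A[i, j] <- 1
            A[j, i] <- 1
          }
        }
      }
      A
    },
    custom = {
      if (is.null(adjacency)) stop("`adjacency` required for kind = 'custom'",
                                   call. = FALSE)
      A <- as.matrix(adjacency)
      if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
      if (any(A < 0)) stop("adjacency must be nonnegative", call. = FALSE)
      if (any(diag(A) != 0)) stop("adjacency must have zero diagonal",
                                  call. = FALSE)
      if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric",
                                            call. = FALSE)
      A
    })
  if (normalize) {
    rs <- rowSums(A)
    pos <- rs > 0
    A[pos, ] <- A[pos, , drop = FALSE] / rs[pos]
  }
  attr(A, "normalized") <- normalize
  A
}
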