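## Grade-of-membership (topic) model for scATAC-seq counts, fitted as a
## Poisson non-negative matrix factorisation by multiplicative-update EM.
##
## Model: x_ij ~ Poisson(lambda_ij), lambda_ij = sum_k L'[i,k] F'[k,j].
## Conditional on cell depth s_i = sum_j x_ij the counts are multinomial with
## probabilities pi_ij = sum_k l_ik f_kj where rows of L and of F sum to 1;
## the Poisson and multinomial parameterisations are related by
## poisson_to_multinomial().

#' Fit a K-topic model to a cell-by-region count matrix
#'
#' Maximises the Poisson-NMF log-likelihood by multiplicative-update EM
#' (each half-update is a monotone majorise-maximise step, so the
#' log-likelihood trace is non-decreasing), then converts the factors to the
#' multinomial (topic) parameterisation.
#'
#' Cells with zero total counts are dropped before fitting and retained in
#' the output with `NA` loadings.
#'
#' @param counts A [cell_region_matrix()] object, or a plain cells x regions
#'   count matrix.
#' @param K Number of topics (>= 1).
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum number of EM iterations.
#' @param tol Convergence tolerance on the relative change in log-likelihood.
#' @param loglik_every Evaluate the log-likelihood (and the convergence
#'   criterion) every this many iterations; 1 gives the full per-iteration
#'   trace, larger values save the cost of the evaluation on big matrices.
#' @param verbose Print the log-likelihood at each evaluation.
#' @return An object of class `scads_topic_fit` with elements `L` (cells x K
#'   loadings, rows sum to 1), `F` (K x regions topic distributions, rows sum
#'   to 1), `Lp`/`Fp` (the Poisson factors), `K`, `loglik_trace` (Poisson
#'   log-likelihood per iteration, constant terms dropped), `converged` and
#'   `barcodes`.
#' @export
fit_topics <- function(counts, K, seed = 1L, max_iter = 500L, tol = 1e-8,
                       loglik_every = 1L, verbose = FALSE) {
  X <- if (inherits(counts, "scads_counts")) counts$counts else counts
  barcodes <- if (inherits(counts, "scads_counts")) counts$barcodes
              else rownames(X) %||% paste0("cell", seq_len(nrow(X)))
  K <- as.integer(K)
  if (K < 1L) stop_format("K must be >= 1")
  if (K > min(dim(X)))
    stop_format("K = %d exceeds min(cells, regions) = %d", K, min(dim(X)))
  depth <- as.numeric(rowSums(X))
  keep <- depth > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-depth cell(s) before fitting",
                    sum(!keep)))
  }
  Xd <- as_dense(X[keep, , drop = FALSE])
  n <- nrow(Xd); J <- ncol(Xd)
  tot <- sum(Xd)

  with_seed(seed, {
    a <- sqrt(tot / (n * K * J))
    Lp <- matrix(runif(n * K, 0.5, 1.5) * a, n, K)
    Fp <- matrix(runif(K * J, 0.5, 1.5) * a, K, J)
  })

  eps <- 1e-12
  nz <- which(Xd > 0)
  xv <- Xd[nz]

  ## Each multiplicative half-update is a monotone majorise-maximise step;
  ## the log-likelihood is evaluated on the current parameters at the top of
  ## an iteration (before the updates), every `loglik_every` iterations, so
  ## the trace is non-decreasing. The factors are clamped away from zero so
  ## all rates stay strictly positive.
  loglik_every <- max(1L, as.integer(loglik_every))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Lam <- Lp %*% Fp
    if ((it - 1L) %% loglik_every == 0L) {
      ll <- sum(xv * log(Lam[nz])) - sum(Lam)
      if (verbose)
        message(sprintf("iter %d: loglik %.6f", it, ll))
      if (length(trace) > 0L) {
        prev <- trace[length(trace)]
        if (abs(ll - prev) < tol * (abs(prev) + 1)) {
          trace <- c(trace, ll)
          converged <- TRUE
          break
        }
      }
      trace <- c(trace, ll)
    }
    ## update L' given F'
    R <- Xd / Lam
    Lp <- pmax(Lp * (R %*% t(Fp)) / rep(rowSums(Fp), each = n), eps)
    ## update F' given new L'
    Lam <- Lp %*% Fp
    R <- Xd / Lam
    Fp <- pmax(Fp * crossprod(Lp, R) / colSums(Lp), eps)
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations; returning best iterate",
                    max_iter))

  mult <- poisson_to_multinomial(list(Lp = Lp, Fp = Fp))
  L <- matrix(NA_real_, length(keep), K)
  Lpfull <- matrix(NA_real_, length(keep), K)
  L[keep, ] <- mult$L
  Lpfull[keep, ] <- Lp
  colnames(L) <- colnames(Lpfull) <- rownames(mult$F) <- paste0("topic", 1:K)
  structure(list(L = L, F = mult$F, Lp = Lpfull, Fp = Fp, K = K,
                 loglik_trace = trace, converged = converged,
                 barcodes = barcodes, kept = keep),
            class = "scads_topic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scads_topic_fit <- function(x, ...) {
  cat(sprintf("scads_topic_fit: %d cells, %d regions, K = %d, %s after %d iterations\n",
              nrow(x$L), ncol(x$F), x$K,
              if (x$converged) "converged" else "not converged",
              length(x$loglik_trace)))
  invisible(x)
}

#' Convert Poisson-NMF factors to the multinomial (topic) parameterisation
#'
#' With Poisson factors `L'` (cells x K) and `F'` (K x regions), the topic
#' distributions are `f_kj = F'[k,j] / u_k` with `u_k = sum_j F'[k,j]`, and
#' the loadings are `l_ik = L'[i,k] u_k / sum_k L'[i,k] u_k`. The model
#' probability `pi_ij = sum_k f_kj l_ik` equals `lambda_ij / sum_k L'[i,k] u_k`,
#' so the conversion leaves the conditional (multinomial) model unchanged.
#'
#' @param fit List with elements `Lp` (cells x K) and `Fp` (K x regions),
#'   non-negative.
#' @return List with `L` (rows sum to 1) and `F` (rows sum to 1).
#' @export
poisson_to_multinomial <- function(fit) {
  Lp <- as.matrix(fit$Lp); Fp <- as.matrix(fit$Fp)
  if (any(Lp < 0) || any(Fp < 0)) stop_format("factors must be non-negative")
  u <- rowSums(Fp)
  if (any(u == 0)) stop_format("topic with all-zero rates")
  Fm <- Fp / u
  Lw <- Lp * rep(u, each = nrow(Lp))
  list(L = row_normalize(Lw), F = Fm)
}

#' Multinomial log-likelihood of a topic fit
#'
#' Computes `sum_ij x_ij log(sum_k f_kj l_ik)` with the multinomial constant
#' dropped; zero counts contribute zero, so all-zero regions leave the value
#' unchanged. Cells with `NA` loadings (zero depth) are skipped.
#'
#' @param counts A `scads_counts` object or count matrix.
#' @param fit A `scads_topic_fit` (or any list with `L` and `F`).
#' @return Scalar log-likelihood; `-Inf` if a positive count has zero model
#'   probability.
#' @export
loglik_topics <- function(counts, fit) {
  X <- if (inherits(counts, "scads_counts")) counts$counts else counts
  X <- as(as(as(Matrix(X, sparse = TRUE), "dMatrix"), "generalMatrix"),
          "TsparseMatrix")
  L <- as.matrix(fit$L); Fm <- as.matrix(fit$F)
  stopifnot(nrow(L) == nrow(X), ncol(Fm) == ncol(X))
  i <- X@i + 1L; j <- X@j + 1L; xv <- X@x
  ok <- !is.na(L[i, 1])
  i <- i[ok]; j <- j[ok]; xv <- xv[ok]
  pi_nz <- rowSums(L[i, , drop = FALSE] * t(Fm)[j, , drop = FALSE])
  if (any(pi_nz == 0 & xv > 0)) return(-Inf)
  sum(xv * log(pi_nz))
}

#' Partition reads into per-topic pseudobulk counts
#'
#' Soft-assigns every read to a topic by its posterior responsibility:
#' `y_kj = sum_i x_ij * l_ik f_kj / sum_k' l_ik' f_k'j`. Reads are conserved:
#' column sums of the pseudobulk equal the column sums of the counts. Regions
#' with zero model probability but positive counts have their reads assigned
#' by loadings alone, with a warning.
#'
#' @param counts A `scads_counts` object or count matrix.
#' @param fit A `scads_topic_fit`.
#' @return K x regions matrix of pseudobulk counts (fractional).
#' @export
pseudobulk_counts <- function(counts, fit) {
  X <- if (inherits(counts, "scads_counts")) counts$counts else counts
  L <- as.matrix(fit$L); Fm <- as.matrix(fit$F)
  stopifnot(nrow(L) == nrow(X), ncol(Fm) == ncol(X))
  keep <- !is.na(L[, 1])
  L <- L[keep, , drop = FALSE]
  Xd <- as_dense(X[keep, , drop = FALSE])
  P <- L %*% Fm
  bad <- which(colSums(P) == 0 & colSums(Xd) > 0)
  W <- Xd / pmax(P, 1e-300)
  Y <- crossprod(L, W) * Fm
  if (length(bad)) {
    warning(sprintf("%d region(s) with zero model probability but positive counts; reads assigned by loadings",
                    length(bad)))
    Y[, bad] <- crossprod(L, Xd[, bad, drop = FALSE])
  }
  rownames(Y) <- rownames(Fm)
  Y
}

#' Loadings-weighted total reads per topic
#'
#' `T_k = sum_i l_ik s_i` with `s_i` the cell depth; the normaliser used to
#' turn baseline counts into rates comparable with the topic distribution.
#'
#' @param counts A `scads_counts` object or count matrix.
#' @param fit A `scads_topic_fit`.
#' @return Numeric vector of length K.
#' @export
topic_total_reads <- function(counts, fit) {
  X <- if (inherits(counts, "scads_counts")) counts$counts else counts
  L <- as.matrix(fit$L)
  keep <- !is.na(L[, 1])
  depth <- as.numeric(rowSums(X))[keep]
  as.numeric(crossprod(L[keep, , drop = FALSE], depth))
}

#' @rdname fit_topics
#' @param x A `scads_topic_fit`.
#' @param ... Unused.
#' @method tidy scads_topic_fit
#' @export
tidy.scads_topic_fit <- function(x, ...) {
  L <- as_tibble(x$L)
  L$barcode <- x$barcodes
  tidyr::pivot_longer(L, -"barcode", names_to = "topic",
                      values_to = "loading")
}

#' @rdname fit_topics
#' @method glance scads_topic_fit
#' @export
glance.scads_topic_fit <- function(x, ...) {
  tibble(K = x$K,
         n_cells = nrow(x$L),
         n_regions = ncol(x$F),
         n_iter = length(x$loglik_trace),
         loglik = tail(x$loglik_trace, 1),
         converged = x$converged)
}
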