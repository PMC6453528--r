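#' Configuration for implicit-feedback ALS factorization
#'
#' The defaults are the standard configuration for literature-network
#' factorization used throughout the package: 20 latent factors, 20
#' alternating sweeps, ridge regularization 0.1 and confidence slope
#' alpha = 0.1. Under the implicit-feedback formulation every cell carries a
#' binary preference p = 1 iff its article count is positive, weighted by a
#' confidence c = 1 + alpha * count, so frequently co-reported gene pairs
#' anchor the fit more strongly than singleton reports.
#'
#' @param rank number of latent factors k.
#' @param iterations number of full alternating sweeps.
#' @param lambda ridge regularization weight (non-negative).
#' @param alpha confidence slope on article counts (non-negative).
#' @param seed integer seed for factor initialization.
#' @param init_scale magnitude of the uniform random initial factors.
#' @param use_counts if `TRUE` (default) confidences grow with article
#'   counts; if `FALSE` the matrix is treated as strictly binary
#'   (c = 1 + alpha for every observed cell).
#' @return an object of class `als_config`.
#' @export
als_config <- function(rank = 20L, iterations = 20L, lambda = 0.1,
                       alpha = 0.1, seed = 1L, init_scale = 0.01,
                       use_counts = TRUE) {
  rank <- as.integer(rank); iterations <- as.integer(iterations)
  stopifnot(rank >= 1L, iterations >= 1L, lambda >= 0, alpha >= 0,
            init_scale > 0)
  structure(list(rank = rank, iterations = iterations, lambda = lambda,
                 alpha = alpha, seed = as.integer(seed),
                 init_scale = init_scale, use_counts = isTRUE(use_counts)),
            class = "als_config")
}

# Confidence weights above baseline for the nonzero cells, as a sparse matrix
# in the same pattern as counts: c_ij - 1 = alpha * counts_ij (or alpha if
# the binary view is requested).
confidence_excess <- function(matrix, config) {
  cm <- matrix$counts
  cm@x <- if (config$use_counts) config$alpha * cm@x
          else rep(config$alpha, length(cm@x))
  cm
}

# One ALS half-step: given the fixed k x n factor `Ffix` whose columns
# correspond to the columns of `excess` (a sparse matrix of c_ij - 1 for
# observed cells, rows corresponding to the factor rows being solved),
# return the m x k matrix of exact ridge solutions
#   w_i = (F C_i F' + lambda I)^-1 F c_i p_i .
solve_half_step <- function(excess, Ffix, lambda) {
  k <- nrow(Ffix)
  G <- tcrossprod(Ffix) + diag(lambda, k)
  ex <- methods::as(excess, "RsparseMatrix")  # row-wise access
  m <- nrow(excess)
  W <- matrix(0, m, k)
  for (i in seq_len(m)) {
    idx <- (ex@p[i] + 1L):ex@p[i + 1L]
    if (ex@p[i + 1L] == ex@p[i]) next  # empty row: ridge solution is zero
    J <- ex@j[idx] + 1L
    cex <- ex@x[idx]
    FJ <- Ffix[, J, drop = FALSE]
    A <- G + FJ %*% (cex * t(FJ))
    b <- FJ %*% (1 + cex)          # p = 1 on observed cells
    R <- chol(A)
    W[i, ] <- backsolve(R, forwardsolve(t(R), b))
  }
  W
}

#' Fit an implicit-feedback ALS factor model
#'
#' Factorizes the interaction matrix into agent factors W (|M| x k) and
#' theme factors H (k x |N|) by minimizing the confidence-weighted objective
#'
#'   sum_ij c_ij (p_ij - W_i . H_j)^2 + lambda (||W||^2 + ||H||^2),
#'
#' with p_ij = 1 iff counts[i, j] > 0 and c_ij = 1 + alpha * counts[i, j],
#' the sum running over all cells. Each sweep performs exact ridge solves for
#' every row of W given H and every column of H given W, so the objective is
#' non-increasing across sweeps. The fit is deterministic given the seed.
#'
#' @param matrix an `interaction_matrix` with at least one nonzero cell.
#' @param config an [als_config()].
#' @return an object of class `factor_model`: list with `W`, `H`, `config`
#'   and `loss_trajectory` (objective after each full sweep).
#' @export
fit_implicit_als <- function(matrix, config = als_config()) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(config, "als_config"))
  m <- nrow(matrix$counts); n <- ncol(matrix$counts)
  if (Matrix::nnzero(matrix$counts) == 0L)
    stop("interaction matrix has no nonzero cells")
  if (config$rank > min(m, n))
    stop(sprintf("rank %d exceeds matrix dimension %d", config$rank, min(m, n)))
  k <- config$rank
  excess <- confidence_excess(matrix, config)
  t_excess <- Matrix::t(excess)

  init <- with_seed(config$seed, {
    list(W = base::matrix(stats::runif(m * k), m, k) * config$init_scale,
         H = base::matrix(stats::runif(k * n), k, n) * config$init_scale)
  })
  W <- init$W; H <- init$H

  loss <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    W <- solve_half_step(excess, H, config$lambda)
    H <- t(solve_half_step(t_excess, t(W), config$lambda))
    if (any(!is.finite(W)) || any(!is.finite(H)))
      stop("non-finite factor values at iteration ", it)
    loss[it] <- als_objective(matrix, W, H, config)
  }
  structure(list(W = W, H = H, config = config, loss_trajectory = loss,
                 genes = matrix$genes),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d x %d, rank %d, final objective %.6g\n",
              nrow(x$W), ncol(x$H), x$config$rank,
              utils::tail(x$loss_trajectory, 1)))
  invisible(x)
}

#' Implicit-feedback ALS objective
#'
#' Evaluates the confidence-weighted squared-error objective over all cells
#' plus ridge penalties. Computed via the Frobenius identity
#' ||WH||^2 = tr((W'W)(HH')) so the zero cells never need materializing.
#'
#' @param matrix an `interaction_matrix`.
#' @param W agents-by-k factor matrix.
#' @param H k-by-themes factor matrix.
#' @param config an [als_config()] supplying lambda and alpha.
#' @return the scalar objective value.
#' @export
als_objective <- function(matrix, W, H, config = als_config()) {
  if (ncol(W) != nrow(H) || nrow(W) != nrow(matrix$counts) ||
      ncol(H) != ncol(matrix$counts))
    stop("factor shapes do not conform to the matrix")
  excess <- confidence_excess(matrix, config)
  ex <- methods::as(excess, "TsparseMatrix")
  i <- ex@i + 1L; j <- ex@j + 1L
  s_obs <- rowSums(W[i, , drop = FALSE] * t(H)[j, , drop = FALSE])
  # baseline weight-1 term over ALL cells: sum s^2 - 2 sum_obs s + n_obs
  base <- sum(crossprod(W) * tcrossprod(H)) - 2 * sum(s_obs) + length(s_obs)
  extra <- sum(ex@x * (1 - s_obs)^2)
  base + extra + config$lambda * (sum(W^2) + sum(H^2))
}

#' Predicted consistency score for a gene pair
#'
#' The reconstructed value of the factorized matrix at (agent, theme):
#' the inner product of the agent's row factor with the theme's column
#' factor. No clamping is applied.
#'
#' @param model a `factor_model`.
#' @param agent,theme gene symbols present in the model.
#' @return a real score.
#' @export
score_pair <- function(model, agent, theme) {
  stopifnot(inherits(model, "factor_model"))
  a <- match(agent, model$genes); b <- match(theme, model$genes)
  if (is.na(a)) stop_unknown_gene(agent, "factor model")
  if (is.na(b)) stop_unknown_gene(theme, "factor model")
  drop(model$W[a, , drop = FALSE] %*% model$H[, b, drop = FALSE])
}

# Full score row/column for one gene without materializing W %*% H.
score_row <- function(model, agent) {
  a <- match(agent, model$genes)
  if (is.na(a)) stop_unknown_gene(agent, "factor model")
  stats::setNames(drop(model$W[a, , drop = FALSE] %*% model$H), model$genes)
}

score_col <- function(model, theme) {
  b <- match(theme, model$genes)
  if (is.na(b)) stop_unknown_gene(theme, "factor model")
  stats::setNames(drop(model$W %*% model$H[, b, drop = FALSE]), model$genes)
}

#' Serialize / restore a factor model as plain text
#'
#' Writes the factor matrices as a whitespace-delimited text container with a
#' shape header, plus a JSON sidecar echoing the configuration.
#' @param model a `factor_model`.
#' @param path output path; the sidecar is written to `<path>.json`.
#' @export
write_factor_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", nrow(model$W), ncol(model$H),
                     model$config$rank), con)
  writeLines(paste(model$genes, collapse = "\t"), con)
  # k columns per line throughout: W row-major, then H transposed
  utils::write.table(format(model$W, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(format(t(model$H), digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(unclass(model$config), list(loss_trajectory = model$loss_trajectory)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  lines <- readLines(path)
  shape <- as.integer(strsplit(lines[1], " ")[[1]])
  genes <- strsplit(lines[2], "\t")[[1]]
  vals <- utils::read.table(text = lines[-(1:2)])
  W <- as.matrix(vals[seq_len(shape[1]), , drop = FALSE])
  H <- t(as.matrix(vals[shape[1] + seq_len(shape[2]), , drop = FALSE]))
  dimnames(W) <- NULL; dimnames(H) <- NULL
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  loss <- cfg$loss_trajectory
  cfg$loss_trajectory <- NULL
  config <- do.call(als_config, cfg)
  structure(list(W = W, H = H, config = config, loss_trajectory = loss,
                 genes = genes), class = "factor_model")
}
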