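# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# SELU constants (self-normalizing networks)
.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

selu <- function(x) {
  ifelse(x > 0, .selu_lambda * x, .selu_lambda * .selu_alpha * (exp(x) - 1))
}

selu_grad <- function(x) {
  ifelse(x > 0, .selu_lambda, .selu_lambda * .selu_alpha * exp(x))
}

# LeCun-normal initialization, the standard companion of SELU.
init_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(1 / fan_in)), fan_in, fan_out)
}

#' Validate a cells x genes expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with rows = cells and columns = genes, finite non-negative
#' entries, and unique row/column identifiers when present.
#'
#' @param m numeric matrix, rows = cells, columns = genes.
#' @param require_names require unique row and column names.
#' @return `m`, invisibly, after validation.
#' @keywords internal
validate_expression_matrix <- function(m, require_names = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression data must be a numeric matrix (cells x genes)", call. = FALSE)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("expression matrix contains negative entries", call. = FALSE)
  }
  if (require_names) {
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("expression matrix must carry cell (row) and gene (column) names", call. = FALSE)
    }
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m))) {
    stop("duplicated cell identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))])[1:min(3, sum(duplicated(rownames(m))))],
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stop("duplicated gene identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))])[1:min(3, sum(duplicated(colnames(m))))],
               collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

# ---- AdamW ------------------------------------------------------------------
# Minimal decoupled-weight-decay Adam. `params` and `grads` are named lists of
# numeric arrays; optimizer state is kept alongside and threaded through calls.

adamw_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-2, decay_on = NULL) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    weight_decay = weight_decay,
    # weight decay applies to weight matrices only, never biases
    decay_on = if (is.null(decay_on)) grep("^W", names(params), value = TRUE) else decay_on,
    t = 0L,
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
}

adamw_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
    if (nm %in% state$decay_on) {
      upd <- upd + state$weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - state$lr * upd
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic minibatch index list for one epoch.
epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + 7919 * k) %% 2147483647)
}

# Pairwise Pearson-similarity helpers; rows of `a` (and `b`) are observations.
row_cor <- function(a, b = NULL) {
  if (is.null(b)) stats::cor(t(a)) else stats::cor(t(a), t(b))
}
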