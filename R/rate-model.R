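#' Constrained Mk rate model
#'
#' A k-state continuous-time Markov (Mk) model of discrete-character
#' evolution. Off-diagonal cells of the instantaneous rate matrix are
#' partitioned into equality classes sharing one rate parameter each;
#' cells may instead be fixed to zero, which is how irreversible (one-way)
#' models are expressed. The diagonal is minus the row sum, so rows of
#' `exp(Qt)` sum to 1 for every `t >= 0`.
#'
#' @param states Character vector of state labels (sorted internally).
#' @param design Integer k x k matrix: 0 on the diagonal and in
#'   zero-fixed cells, and class ids `1..p` elsewhere. Defaults to the
#'   all-rates-different model.
#' @param rates Numeric vector of length `p` (one rate per class), in
#'   expected events per unit branch length; default 1.
#' @param root_prior `"uniform"`, `"stationary"`, or a probability vector
#'   of length k.
#' @return An object of class `"rate_model"`.
#' @examples
#' # binary specialist/generalist models (states sorted: G, S)
#' rate_model(c("G", "S"))                              # 2-rate bidirectional
#' rate_model(c("G", "S"), design = matrix(c(0, 0, 1, 0), 2))  # G->S only
#' @export
rate_model <- function(states, design = NULL, rates = NULL,
                       root_prior = c("uniform", "stationary")) {
  states <- sort(unique(as.character(states)))
  k <- length(states)
  if (k < 2L) stop("need at least 2 states")
  if (is.null(design)) {
    # all-rates-different, classes numbered row-major: q1 = 1->2, q2 = 1->3, ...
    design <- matrix(0L, k, k)
    id <- 0L
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j) { id <- id + 1L; design[i, j] <- id }
      }
    }
  }
  design <- matrix(as.integer(design), k, k)
  if (any(diag(design) != 0L)) stop("design diagonal must be 0")
  p <- max(design)
  off <- design[row(design) != col(design)]
  if (p > 0L && !setequal(setdiff(unique(off), 0L), seq_len(p))) {
    stop("design class ids must be 0 (fixed zero) or 1..p without gaps")
  }
  if (is.null(rates)) rates <- rep(1, max(p, 1L)) else rates <- as.numeric(rates)
  if (p > 0L && length(rates) != p) stop("need ", p, " rates, got ", length(rates))
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and >= 0")
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior)
  } else {
    root_prior <- as.numeric(root_prior)
    if (length(root_prior) != k || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-8) {
      stop("fixed root prior must be a length-", k, " probability vector")
    }
  }
  structure(list(states = states, k = k, design = design, rates = rates,
                 n_free = p, root_prior = root_prior),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Mk rate model:", x$k, "states (", paste(x$states, collapse = ", "),
      "),", x$n_free, "free rate class(es)\n")
  Q <- rate_matrix(x)
  dimnames(Q) <- list(x$states, x$states)
  print(round(Q, 6))
  invisible(x)
}

#' Instantaneous rate matrix Q of a model
#'
#' @param model A [rate_model()].
#' @param rates Optional replacement rates (length `model$n_free`).
#' @return The k x k generator matrix (rows sum to 0).
#' @export
rate_matrix <- function(model, rates = NULL) {
  if (is.null(rates)) rates <- model$rates
  k <- model$k
  Q <- matrix(0, k, k)
  nz <- model$design > 0L
  Q[nz] <- rates[model$design[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Update the free rates of a model
#' @param model A [rate_model()].
#' @param rates Numeric vector of length `model$n_free`.
#' @return The model with rates replaced.
#' @export
set_rates <- function(model, rates) {
  stopifnot(length(rates) == model$n_free, all(is.finite(rates)), all(rates >= 0))
  model$rates <- as.numeric(rates)
  model
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Closed form for two states; eigendecomposition for k > 2, with a
#' scaling-and-squaring series fallback when the generator is defective.
#'
#' @param model A [rate_model()] (or a bare generator matrix).
#' @param t Non-negative duration in branch-length units.
#' @return Row-stochastic k x k matrix of state-transition probabilities.
#' @examples
#' m <- rate_model(c("0", "1"), rates = c(1, 2))
#' transition_matrix(m, 1)[1, 2]  # (1/3) * (1 - exp(-3))
#' @export
transition_matrix <- function(model, t) {
  Q <- if (inherits(model, "rate_model")) rate_matrix(model) else model
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single non-negative number")
  }
  if (any(!is.finite(Q))) stop("non-finite rates")
  expQt(Q, t)
}

#' @keywords internal
expQt <- function(Q, t) {
  k <- nrow(Q)
  if (t == 0 || all(Q == 0)) return(diag(k))
  if (k == 2L) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    e <- exp(-s * t)
    P <- matrix(c(b + a * e, b - b * e, a - a * e, a + b * e), 2, 2) / s
    return(P)
  }
  ev <- eigen(Q)
  P <- NULL
  if (all(abs(Im(ev$values)) < 1e-9)) {
    V <- Re(ev$vectors)
    cn <- tryCatch(kappa(V), error = function(e) Inf)
    if (is.finite(cn) && cn < 1e8) {
      P <- Re(V %*% (exp(Re(ev$values) * t) * solve(V)))
    }
  }
  if (is.null(P)) P <- expm_ss(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

# scaling-and-squaring Taylor series fallback for defective generators
#' @keywords internal
expm_ss <- function(A, order = 16L) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, max(abs(A))))) + 1L)
  B <- A / 2^s
  P <- diag(n); term <- diag(n)
  for (i in seq_len(order)) {
    term <- term %*% B / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Stationary distribution of a rate model
#' @param model A [rate_model()] or generator matrix.
#' @return Probability vector pi with pi Q = 0.
#' @export
stationary_distribution <- function(model) {
  Q <- if (inherits(model, "rate_model")) rate_matrix(model) else model
  k <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / k, k))
  A <- rbind(t(Q), rep(1, k))
  pi <- tryCatch(qr.solve(A, c(rep(0, k), 1)), error = function(e) NULL)
  if (is.null(pi) || any(pi < -1e-8)) {
    # absorbing / reducible generators: take the long-run limit instead
    P <- expQt(Q, 1e6 / max(abs(Q)))
    pi <- colMeans(P)
  }
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Root prior probabilities of a model
#' @keywords internal
root_prior_vector <- function(model) {
  rp <- model$root_prior
  if (is.numeric(rp)) return(rp)
  switch(rp,
         uniform = rep(1 / model$k, model$k),
         stationary = stationary_distribution(model))
}
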