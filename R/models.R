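# Nucleotide substitution models (JC69, K80, HKY85): rate matrices,
# transition probabilities, and BIC model selection.

NUC <- c("A", "C", "G", "T")

#' Construct a substitution model
#'
#' Time-reversible nucleotide models with the rate matrix scaled to one
#' expected substitution per site per unit branch length. `JC69` has equal
#' rates and frequencies; `K80` adds a transition/transversion ratio
#' `kappa`; `HKY85` additionally takes unequal base frequencies `pi`.
#'
#' @param name `"JC69"`, `"K80"` or `"HKY85"`
#' @param kappa transition/transversion rate ratio (> 0; ignored for JC69)
#' @param pi base frequencies in A, C, G, T order (HKY85 only; must sum
#'   to 1)
#' @return object of class `subst_model` with the scaled rate matrix `Q`,
#'   its symmetric eigendecomposition (for fast `P(t)`), and the free
#'   parameter count `n_free`
#' @export
substitution_model <- function(name = c("JC69", "K80", "HKY85"),
                               kappa = 1, pi = rep(0.25, 4)) {
  name <- match.arg(name)
  if (kappa <= 0) stop("kappa must be > 0")
  if (name != "HKY85") pi <- rep(0.25, 4)
  if (name == "JC69") kappa <- 1
  pi <- pi / sum(pi)
  if (any(pi <= 0)) stop("base frequencies must be positive")
  names(pi) <- NUC

  is_transition <- matrix(FALSE, 4, 4, dimnames = list(NUC, NUC))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(NUC, NUC))
  Q[is_transition] <- Q[is_transition] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))           # expected rate; scale to 1
  Q <- Q / mu

  # reversible Q: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    name = name, kappa = kappa, pi = pi, Q = Q,
    eval = eig$values,
    right = diag(1 / sp) %*% eig$vectors,
    left = t(eig$vectors) %*% diag(sp),
    n_free = switch(name, JC69 = 0L, K80 = 1L, HKY85 = 4L)
  ), class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a [substitution_model]
#' @param t branch length (expected substitutions/site, >= 0)
#' @return 4x4 matrix, rows = from-state, columns = to-state
#' @export
transition_prob <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$right %*% (exp(model$eval * t) * model$left)
  # numerical cleanup: probabilities in [0,1], rows sum to 1
  P[P < 0] <- 0
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Empirical base frequencies of an alignment
#' @param aln a `pseudo_alignment`
#' @return frequency vector over A, C, G, T
#' @export
base_frequencies <- function(aln) {
  tab <- table(factor(aln$chars, levels = NUC))
  f <- as.numeric(tab)
  if (sum(f) == 0) stop("alignment has no A/C/G/T characters")
  f <- (f + 0.5) / sum(f + 0.5)   # light smoothing keeps frequencies positive
  names(f) <- NUC
  f
}

#' Select a substitution model by BIC
#'
#' Fits each candidate on a fixed starting topology (neighbor joining on
#' JC-corrected distances), optimizing branch lengths and, where present,
#' `kappa` (HKY85 uses empirical base frequencies). BIC = -2 lnL + k ln(n)
#' with n the number of alignment columns and k counting branch lengths
#' plus model parameters; the candidate with the smallest BIC wins.
#'
#' @param aln a `pseudo_alignment`
#' @param candidates character vector of model names
#' @return list with `model` (fitted `subst_model`), `tree` (the fitted
#'   starting tree under the winner) and `table` (per-candidate data.frame:
#'   `model`, `logLik`, `k`, `BIC`)
#' @export
select_model <- function(aln, candidates = c("JC69", "K80", "HKY85")) {
  if (length(candidates) == 0) stop("empty candidate list")
  tree <- starting_tree(aln)
  n <- ncol(aln$chars)
  n_branch <- nrow(tree$edge)
  emp_pi <- base_frequencies(aln)

  fits <- lapply(candidates, function(nm) {
    model <- substitution_model(nm, pi = emp_pi)
    fit <- optimize_model(tree, aln, model)
    k <- n_branch + model$n_free
    list(model = fit$model, tree = fit$tree, logLik = fit$logLik, k = k,
         BIC = -2 * fit$logLik + k * log(n))
  })
  tab <- data.frame(
    model = candidates,
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    stringsAsFactors = FALSE
  )
  best <- which.min(tab$BIC)
  list(model = fits[[best]]$model, tree = fits[[best]]$tree, table = tab)
}

# NJ starting topology on JC-corrected Hamming distances.
starting_tree <- function(aln) {
  x <- aln$chars
  ntax <- nrow(x)
  if (ntax < 4) {
    tr <- star_tree(rownames(x))
    return(tr)
  }
  p <- matrix(0, ntax, ntax)
  for (i in seq_len(ntax - 1)) {
    for (j in (i + 1):ntax) {
      p[i, j] <- p[j, i] <- mean(x[i, ] != x[j, ])
    }
  }
  p[p > 0.70] <- 0.70
  d <- -3 / 4 * log(1 - 4 * p / 3)
  dimnames(d) <- list(rownames(x), rownames(x))
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  ape::unroot(tr)
}

star_tree <- function(taxa) {
  n <- length(taxa)
  txt <- paste0("(", paste(taxa, collapse = ","), ");")
  tr <- ape::read.tree(text = txt)
  tr$edge.length <- rep(0.05, nrow(tr$edge))
  tr
}

# Alternate kappa and branch-length optimization for one model on a fixed
# topology; returns fitted model, tree and lnL.
optimize_model <- function(tree, aln, model, n_rounds = 3) {
  fit <- optimize_branch_lengths(tree, aln, model)
  tree <- fit$tree
  ll <- fit$logLik
  if (model$n_free > 0) {
    for (r in seq_len(n_rounds)) {
      opt <- stats::optimize(function(lk) {
        m <- substitution_model(model$name, kappa = exp(lk), pi = model$pi)
        tree_loglik(tree, aln, m)
      }, interval = log(c(0.05, 100)), maximum = TRUE, tol = 1e-4)
      model <- substitution_model(model$name, kappa = exp(opt$maximum),
                                  pi = model$pi)
      fit <- optimize_branch_lengths(tree, aln, model)
      tree <- fit$tree
      if (fit$logLik - ll < 1e-4) {
        ll <- fit$logLik
        break
      }
      ll <- fit$logLik
    }
  }
  list(model = model, tree = tree, logLik = ll)
}
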