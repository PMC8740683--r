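#' Annotate SNPs by proximity to a network
#'
#' \code{a_j = 1} when SNP j lies within a closed +/- \code{window} of any
#' regulatory element or any target gene's body of the network
#' (\code{mode = "network"}), or of any gene in \code{genes}
#' (\code{mode = "near_gene"}, the near-gene control annotation).
#'
#' @param snps \code{GRanges} of SNP positions (width 1).
#' @param network a \code{RETGNetwork} (for \code{mode = "network"}).
#' @param genes named \code{GRanges} of protein-coding gene bodies (for
#'   \code{mode = "near_gene"}).
#' @param window flanking window in bp (50 kb by default), closed at the
#'   boundary.
#' @param mode \code{"network"} or \code{"near_gene"}.
#' @return integer 0/1 vector, one entry per SNP.
#' @export
annotateSnps <- function(snps, network = NULL, genes = NULL,
                         window = 50000L, mode = c("network", "near_gene")) {
  mode <- match.arg(mode)
  if (mode == "network") {
    stopifnot(!is.null(network))
    ed <- networkEdges(network)
    ## the network proper is the loop-linked part: its target genes and
    ## every RE (anchor tile or promoter) attached to them
    tg <- unique(ed$gene[!is.na(ed$loop)])
    reIds <- unique(ed$re_id[ed$gene %in% tg])
    el <- regulatoryElements(network)
    feats <- suppressWarnings(c(granges(el[el$re_id %in% reIds]),
                                granges(network@geneRanges[tg])))
  } else {
    stopifnot(!is.null(genes))
    feats <- granges(genes)
  }
  if (length(feats) == 0L) return(integer(length(snps)))
  known <- as.character(seqnames(snps)) %in%
    unique(as.character(seqnames(feats)))
  if (!all(known))
    warning(sum(!known), " SNPs on chromosomes absent from the network; ",
            "annotated 0")
  feats <- suppressWarnings(resize(feats, width = width(feats) + 2 * window,
                                   fix = "center"))
  start(feats) <- pmax(start(feats), 1L)
  strand(feats) <- "*"
  snpsU <- snps
  strand(snpsU) <- "*"
  as.integer(quietCountOverlaps(snpsU, feats) > 0 & known)
}

#' Per-SNP prior from the enrichment hyperparameters
#'
#' Under the spike-and-slab effect-size prior, SNP j is causal with
#' probability \eqn{\pi_j = \theta_0 + a_j \theta} and its effect, when
#' nonzero, has variance \eqn{\sigma_j^2 = \sigma_0^2 + a_j \sigma^2}.
#'
#' @param theta0 baseline inclusion probability.
#' @param theta enrichment shift (>= 0).
#' @param sigma0sq baseline slab variance (>= 0).
#' @param sigmasq enrichment variance shift (>= 0).
#' @param a 0/1 annotation vector (or scalar).
#' @return list with \code{pi} and \code{sigma2} vectors.
#' @export
priorAt <- function(theta0, theta, sigma0sq, sigmasq, a) {
  pi <- theta0 + a * theta
  if (any(pi <= 0 | pi >= 1))
    stop("grid misconfiguration: pi_j must lie in (0, 1)")
  list(pi = pi, sigma2 = sigma0sq + a * sigmasq)
}

#' Default hyperparameter grid
#'
#' Cartesian grid over theta0, theta, sigma0sq (scaled by 1/n) and sigmasq
#' (as multiples of sigma0sq). All values are configurable; the defaults
#' span weak to moderate enrichment at GWAS effect scales.
#'
#' @param n GWAS sample size (scales the slab variance).
#' @param theta0,theta,sigma0sqScaled,sigmasqMult grid axes;
#'   \code{sigma0sq = sigma0sqScaled / n}, \code{sigmasq = sigmasqMult *
#'   sigma0sq}.
#' @return \code{data.frame} grid with columns \code{theta0}, \code{theta},
#'   \code{sigma0sq}, \code{sigmasq}.
#' @export
defaultGrid <- function(n,
                        theta0 = c(1e-4, 1e-3, 1e-2, 0.05),
                        theta = c(0, 1e-3, 1e-2, 0.05),
                        sigma0sqScaled = c(0.01, 0.05, 0.1),
                        sigmasqMult = c(0, 0.5, 1, 2)) {
  g <- expand.grid(theta0 = theta0, theta = theta,
                   sigma0sqScaled = sigma0sqScaled,
                   sigmasqMult = sigmasqMult,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(theta0 = g$theta0, theta = g$theta,
             sigma0sq = g$sigma0sqScaled / n,
             sigmasq = g$sigmasqMult * g$sigma0sqScaled / n)
}

## shared per-dataset quantities for the summary-statistics likelihood
rssPrecompute <- function(betahat, se, R) {
  stopifnot(length(betahat) == length(se), all(se > 0),
            nrow(R) == length(betahat), isSymmetric(unname(R)))
  p <- length(betahat)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    R <- R + diag(1e-6, p)
    ch <- chol(R)
  }
  H <- R / tcrossprod(se)          # S^{-1} R S^{-1}
  b <- betahat / se^2
  u <- backsolve(ch, betahat / se, transpose = TRUE)
  quad <- sum(u^2)                  # betahat' Sigma^{-1} betahat
  logdet <- 2 * sum(log(se)) + 2 * sum(log(diag(ch)))
  const <- -0.5 * (p * log(2 * pi) + logdet + quad)
  list(H = H, b = b, const = const, R = R)
}

#' Fit the enrichment model over a hyperparameter grid
#'
#' For every grid point the spike-and-slab posterior is approximated by
#' mean-field coordinate-ascent variational inference under the
#' summary-statistics likelihood
#' \eqn{\hat\beta \mid \beta \sim N(S R S^{-1}\beta,\; S R S)} with
#' \eqn{S = diag(s_j)}. The converged evidence lower bound serves as the
#' approximate log marginal likelihood of the grid point. SNPs are updated
#' in order of decreasing \eqn{|\hat\beta_j / s_j|} (fixed, for
#' determinism); convergence is a relative ELBO change below \code{tol}.
#'
#' @param stats \code{data.frame} with columns \code{betahat}, \code{se}
#'   (and optionally \code{snp_id}, \code{n}).
#' @param ld LD correlation matrix (unit diagonal; regularized by adding
#'   1e-6 to the diagonal if not positive definite).
#' @param annotation 0/1 vector from \code{\link{annotateSnps}}.
#' @param grid hyperparameter grid (see \code{\link{defaultGrid}}).
#' @param tol relative ELBO convergence tolerance.
#' @param maxit maximum coordinate-ascent sweeps per grid point.
#' @return an \code{\link{EnrichmentFit-class}} object. Non-converged points
#'   are flagged and excluded from model averaging by
#'   \code{\link{bayesFactor}} with a warning.
#' @export
fitGrid <- function(stats, ld, annotation, grid, tol = 1e-7, maxit = 1000L) {
  stopifnot(nrow(grid) >= 1L, length(annotation) == nrow(stats))
  pre <- rssPrecompute(stats$betahat, stats$se, as.matrix(ld))
  p <- nrow(stats)
  ord <- order(abs(stats$betahat / stats$se), decreasing = TRUE) - 1L
  logml <- numeric(nrow(grid))
  pip <- matrix(NA_real_, nrow = p, ncol = nrow(grid))
  conv <- logical(nrow(grid))
  nit <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pr <- priorAt(grid$theta0[g], grid$theta[g],
                  grid$sigma0sq[g], grid$sigmasq[g], annotation)
    fit <- rssVarbvsFit(pre$H, pre$b, pr$pi, pr$sigma2,
                        as.integer(ord), pre$const, tol, as.integer(maxit))
    if (!fit$monotone)
      warning("ELBO decreased during coordinate ascent at grid point ", g)
    logml[g] <- fit$logml
    pip[, g] <- fit$alpha
    conv[g] <- fit$converged
    nit[g] <- fit$niter
  }
  if (any(!conv))
    warning(sum(!conv), " grid points did not converge within ", maxit,
            " iterations; they are excluded from model averaging")
  new("EnrichmentFit", grid = as.data.frame(grid), logml = logml, pip = pip,
      converged = conv, niter = nit)
}

## grid-point selectors for the enrichment model hierarchy
modelConstraint <- function(grid, model) {
  switch(model,
         M0 = grid$theta == 0 & grid$sigmasq == 0,
         M11 = grid$theta > 0 & grid$sigmasq == 0,
         M12 = grid$theta > 0 & grid$sigmasq > 0,
         M1 = grid$theta > 0 | grid$sigmasq > 0,
         stop("unknown model ", model))
}

#' Bayes factor of an enrichment model against a baseline
#'
#' The marginal likelihood of a model is the arithmetic mean (uniform prior
#' over the grid) of \code{exp(logML)} over the grid points its constraint
#' allows; the Bayes factor is the ratio of model to baseline means,
#' computed in log space.
#'
#' @param fit an \code{EnrichmentFit}.
#' @param model \code{"M1"}, \code{"M11"} or \code{"M12"} (\code{"M0"} gives
#'   1 against itself).
#' @param baseline baseline model, \code{"M0"} by default.
#' @return the Bayes factor (numeric scalar).
#' @export
bayesFactor <- function(fit, model, baseline = "M0") {
  grid <- hyperGrid(fit)
  keep <- fit@converged
  lm <- gridLogML(fit)
  num <- modelConstraint(grid, model) & keep
  den <- modelConstraint(grid, baseline) & keep
  if (!any(num)) stop("no converged grid points satisfy model ", model)
  if (!any(den)) stop("no converged grid points satisfy model ", baseline)
  exp(logMeanExp(lm[num]) - logMeanExp(lm[den]))
}

#' Exact marginal likelihood by enumeration (test oracle)
#'
#' Computes the exact log marginal likelihood of each grid point by summing
#' over all \eqn{2^p} inclusion configurations with analytic Gaussian
#' integration over the included effects, and the model-level Bayes factor
#' with the same grid averaging as \code{\link{bayesFactor}}. Only feasible
#' for small SNP panels.
#'
#' @param stats,ld,annotation,grid as in \code{\link{fitGrid}}.
#' @param model,baseline as in \code{\link{bayesFactor}}.
#' @return list with \code{logml} per grid point and \code{bf}.
#' @export
exactBFOracle <- function(stats, ld, annotation, grid,
                          model = "M11", baseline = "M0") {
  p <- nrow(stats)
  if (p > 12L) stop("exact enumeration refuses p > 12")
  pre <- rssPrecompute(stats$betahat, stats$se, as.matrix(ld))
  R <- pre$R
  se <- stats$se
  M <- R * outer(se, 1 / se)       # S R S^{-1}
  Sigma <- R * tcrossprod(se)      # S R S
  betahat <- stats$betahat
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  logml <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pr <- priorAt(grid$theta0[g], grid$theta[g],
                  grid$sigma0sq[g], grid$sigmasq[g], annotation)
    terms <- apply(configs, 1, function(gam) {
      lp <- sum(log(ifelse(gam, pr$pi, 1 - pr$pi)))
      D <- ifelse(gam, pr$sigma2, 0)
      V <- Sigma + M %*% (D * t(M))
      ch <- chol((V + t(V)) / 2)
      u <- backsolve(ch, betahat, transpose = TRUE)
      lp - 0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
    })
    m <- max(terms)
    logml[g] <- m + log(sum(exp(terms - m)))
  }
  num <- modelConstraint(grid, model)
  den <- modelConstraint(grid, baseline)
  list(logml = logml,
       bf = exp(logMeanExp(logml[num]) - logMeanExp(logml[den])))
}
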