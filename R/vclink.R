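#' Assemble per-family data for variance-component linkage
#'
#' Packs, for each family, the adjusted trait vector, the kinship matrix and
#' the locus IBD matrix in a common member order.
#'
#' @param peds named list of pedigrees.
#' @param y named numeric of adjusted trait values (names = individual ids)
#'   for a single replicate.
#' @param ibd named list of per-family IBD matrices (as from [geneIBD()]).
#' @return list of per-family lists with elements \code{famID}, \code{y},
#'   \code{Phi}, \code{Pi}.
#' @export
vcFamilies <- function(peds, y, ibd) {
  lapply(peds, function(p) {
    ids <- members(p)$id
    if (!all(ids %in% names(y)))
      stop(sprintf("missing trait values for family %s", famID(p)))
    list(famID = famID(p), y = unname(y[ids]),
         Phi = kinship(p), Pi = ibd[[famID(p)]][ids, ids])
  })
}

# covariance of one family at the given components
omegaFam <- function(fam, s2q, s2a, s2e) {
  n <- length(fam$y)
  s2q * fam$Pi + 2 * s2a * fam$Phi + s2e * diag(n)
}

# log-likelihood contribution of one family; jitters near-singular covariance
famLoglik <- function(fam, mu, s2q, s2a, s2e) {
  om <- omegaFam(fam, s2q, s2a, s2e)
  L <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(L) || rcond(L) < 1e-12) {
    om <- om + diag(1e-8, nrow(om))
    L <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(L))
      stop(sprintf("covariance matrix not positive definite in family %s",
                   fam$famID))
  }
  d <- fam$y - mu
  z <- backsolve(L, d, transpose = TRUE)
  -0.5 * (length(d) * log(2 * pi)) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Variance-component log-likelihood
#'
#' Total multivariate-normal log-likelihood over independent families with
#' covariance \eqn{\Omega_f = \sigma^2_q \Pi_f + 2\sigma^2_a \Phi_f +
#' \sigma^2_e I}.
#'
#' @param params named numeric: \code{mu}, \code{sigma2_q}, \code{sigma2_a},
#'   \code{sigma2_e} (variances >= 0).
#' @param families per-family data from [vcFamilies()].
#' @param perFamily if \code{TRUE} return the vector of per-family
#'   contributions instead of their sum.
#' @return log-likelihood in nats.
#' @export
vcLoglik <- function(params, families, perFamily = FALSE) {
  stopifnot(all(c("mu", "sigma2_q", "sigma2_a", "sigma2_e") %in% names(params)))
  ll <- vapply(families, famLoglik, 0.0, mu = params[["mu"]],
               s2q = params[["sigma2_q"]], s2a = params[["sigma2_a"]],
               s2e = params[["sigma2_e"]])
  names(ll) <- vapply(families, `[[`, "", "famID")
  if (perFamily) ll else sum(ll)
}

dataFingerprint <- function(families) {
  sprintf("%d:%.10g", sum(vapply(families, function(f) length(f$y), 0L)),
          sum(vapply(families, function(f) sum(f$y) + sum(f$Pi), 0.0)))
}

# loglik and analytic gradient of one family at (mu, s2q, s2a, s2e);
# gradient in variance units (chain rule to log scale is applied by caller)
famLoglikGrad <- function(fam, mu, s2q, s2a, s2e) {
  om <- omegaFam(fam, s2q, s2a, s2e)
  L <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(L)) {
    om <- om + diag(1e-8, nrow(om))
    L <- chol(om)
  }
  n <- length(fam$y)
  d <- fam$y - mu
  oi <- chol2inv(L)
  u <- oi %*% d
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(d * u)
  gcomp <- function(A) -0.5 * sum(oi * A) + 0.5 * sum(u * (A %*% u))
  c(ll = ll,
    mu = sum(u),
    s2q = gcomp(fam$Pi),
    s2a = 2 * gcomp(fam$Phi),
    s2e = -0.5 * sum(diag(oi)) + 0.5 * sum(u^2))
}

#' Fit the variance-component model by maximum likelihood
#'
#' Optimizes \eqn{(\mu, \sigma^2_q, \sigma^2_a, \sigma^2_e)} on the
#' log-variance scale from three starting variance splits of the trait
#' variance — (0.1, 0.8, 0.1), (0.3, 0.3, 0.4) and (0, 0.5, 0.5) for
#' (QTL, polygenic, environmental) — keeping the best optimum. The full model
#' additionally probes the \eqn{\sigma^2_q = 0} boundary by fitting the null
#' model, so the returned full-model likelihood is never below the null's.
#'
#' @param families per-family data from [vcFamilies()].
#' @param model \code{"full"} or \code{"null"} (null constrains
#'   \eqn{\sigma^2_q = 0}).
#' @param control list: \code{factr} L-BFGS-B tolerance factor.
#' @param nullFit optional pre-computed null-model [VCFit-class] on the same
#'   data, reused for the full model's boundary probe.
#' @return a [VCFit-class] object.
#' @export
vcFit <- function(families, model = c("full", "null"), control = list(),
                  nullFit = NULL) {
  model <- match.arg(model)
  y <- unlist(lapply(families, `[[`, "y"), use.names = FALSE)
  vy <- stats::var(y)
  mu0 <- mean(y)
  splits <- list(c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4), c(1e-4, 0.5, 0.5))
  lb <- log(vy) - 25
  ub <- log(vy) + 6
  full <- model == "full"
  unpack <- if (full)
    function(th) c(mu = th[1L], sigma2_q = exp(th[2L]),
                   sigma2_a = exp(th[3L]), sigma2_e = exp(th[4L]))
  else
    function(th) c(mu = th[1L], sigma2_q = 0,
                   sigma2_a = exp(th[2L]), sigma2_e = exp(th[3L]))
  evalBoth <- function(th) {
    p <- unpack(th)
    gs <- vapply(families, famLoglikGrad, numeric(5), mu = p[["mu"]],
                 s2q = p[["sigma2_q"]], s2a = p[["sigma2_a"]],
                 s2e = p[["sigma2_e"]])
    tot <- rowSums(gs)
    # chain rule: d/d log sigma2 = sigma2 * d/d sigma2
    gr <- if (full)
      c(tot[["mu"]], tot[["s2q"]] * p[["sigma2_q"]],
        tot[["s2a"]] * p[["sigma2_a"]], tot[["s2e"]] * p[["sigma2_e"]])
    else
      c(tot[["mu"]], tot[["s2a"]] * p[["sigma2_a"]],
        tot[["s2e"]] * p[["sigma2_e"]])
    list(value = -tot[["ll"]], grad = -gr)
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    cache$last <- evalBoth(th); cache$th <- th
    cache$last$value
  }
  gr <- function(th) {
    if (is.null(cache$th) || !identical(th, cache$th))
      fn(th)
    cache$last$grad
  }
  best <- NULL
  for (sp in splits) {
    par0 <- if (full) c(mu0, log(vy * pmax(sp, 1e-6)))
            else c(mu0, log(vy * pmax(sp[2:3], 1e-4)))
    np <- length(par0)
    opt <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   lower = c(-Inf, rep(lb, np - 1L)),
                   upper = c(Inf, rep(ub, np - 1L)),
                   control = list(factr = control$factr %||% 1e6,
                                  maxit = 500L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$converged <- opt$convergence == 0L
    }
  }
  if (is.null(best))
    stop("variance-component optimization failed from every start")
  th <- best$par
  params <- unpack(th)
  if (full) {
    # boundary probe at sigma2_q = 0
    nul <- if (!is.null(nullFit)) nullFit else vcFit(families, "null", control)
    stopifnot(nul@model == "null",
              nul@fingerprint == dataFingerprint(families))
    if (nul@loglik > -best$value) {
      params <- vcParams(nul)
      best$value <- -nul@loglik
      best$converged <- converged(nul)
    }
  }
  # clamp negligible variance components to the boundary
  tiny <- params[c("sigma2_q", "sigma2_a", "sigma2_e")] < vy * 1e-9
  params[c("sigma2_q", "sigma2_a", "sigma2_e")][tiny] <- 0
  fl <- vcLoglik(params, families, perFamily = TRUE)
  new("VCFit", params = params, loglik = sum(fl), familyLoglik = fl,
      converged = best$converged, model = model,
      fingerprint = dataFingerprint(families))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LOD score from nested variance-component fits
#'
#' \eqn{(\ln L_{full} - \ln L_{null}) / \ln 10}, floored at zero when within
#' \code{1e-6} below it (nested-model numerics).
#'
#' @param fitFull,fitNull [VCFit-class] objects for the same data.
#' @return LOD score in log10 units.
#' @export
lodScore <- function(fitFull, fitNull) {
  stopifnot(is(fitFull, "VCFit"), is(fitNull, "VCFit"),
            fitFull@model == "full", fitNull@model == "null")
  if (fitFull@fingerprint != fitNull@fingerprint)
    stop("full and null fits were computed on different data")
  lod <- (fitFull@loglik - fitNull@loglik) / log(10)
  if (lod < 0 && lod > -1e-6) lod <- 0
  lod
}

#' Family-specific LOD decomposition
#'
#' Each family's LOD is its log-likelihood-ratio contribution with both
#' models evaluated at the whole-sample maximum-likelihood estimates (no
#' per-family re-maximization), so the contributions sum to the total LOD.
#'
#' @param fitFull,fitNull [VCFit-class] objects for the same data.
#' @return a [FamilyLODProfile-class] object.
#' @export
familyLOD <- function(fitFull, fitNull) {
  stopifnot(fitFull@model == "full", fitNull@model == "null")
  if (fitFull@fingerprint != fitNull@fingerprint)
    stop("full and null fits were computed on different data")
  fl <- (fitFull@familyLoglik - fitNull@familyLoglik) / log(10)
  new("FamilyLODProfile", familyLOD = fl, totalLOD = sum(fl))
}

#' Expected LOD score under the null
#'
#' Under the boundary null of \eqn{\sigma^2_q = 0} the LOD is distributed as
#' a half-half mixture of \eqn{\chi^2_1 / (2 \ln 10)} and a point mass at 0,
#' whose mean is \eqn{1 / (4 \ln 10) \approx 0.1086} (0.11 to two decimals).
#'
#' @return the expected null LOD (log10 units).
#' @export
nullExpectedLod <- function() 1 / (4 * log(10))

#' Draw LOD scores from the null mixture
#'
#' @param n number of draws.
#' @return numeric vector: 0 with probability 1/2, else
#'   \eqn{\chi^2_1 / (2 \ln 10)}.
#' @export
rLODNull <- function(n) {
  z <- stats::rchisq(n, df = 1) / (2 * log(10))
  ifelse(stats::runif(n) < 0.5, 0, z)
}

#' P-value of a LOD score under the null mixture
#'
#' \eqn{p = \frac{1}{2} P(\chi^2_1 \ge 2 \ln 10 \cdot LOD)} for positive LOD;
#' 0.5 at LOD = 0.
#'
#' @param lod non-negative LOD score.
#' @return one-sided p-value.
#' @export
lodPvalue <- function(lod) {
  if (any(lod < 0)) stop("LOD must be non-negative")
  ifelse(lod == 0, 0.5,
         0.5 * stats::pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE))
}

#' @rdname VCFit-class
#' @export
setMethod("vcParams", "VCFit", function(x) x@params)

#' @rdname VCFit-class
#' @export
setMethod("fitLoglik", "VCFit", function(x) x@loglik)

#' @rdname VCFit-class
#' @export
setMethod("familyLoglik", "VCFit", function(x) x@familyLoglik)

#' @rdname VCFit-class
#' @export
setMethod("converged", "VCFit", function(x) x@converged)

setMethod("show", "VCFit", function(object) {
  p <- object@params
  cat(sprintf("VCFit (%s model): logLik = %.4f%s\n", object@model,
              object@loglik, if (object@converged) "" else " (not converged)"))
  cat(sprintf("  mu = %.4f, sigma2_q = %.4f, sigma2_a = %.4f, sigma2_e = %.4f\n",
              p[["mu"]], p[["sigma2_q"]], p[["sigma2_a"]], p[["sigma2_e"]]))
})

#' @rdname FamilyLODProfile-class
#' @export
setMethod("familyLODs", "FamilyLODProfile", function(x) x@familyLOD)

#' @rdname FamilyLODProfile-class
#' @export
setMethod("totalLOD", "FamilyLODProfile", function(x) x@totalLOD)

setMethod("show", "FamilyLODProfile", function(object) {
  cat(sprintf("FamilyLODProfile: total LOD = %.4f over %d families\n",
              object@totalLOD, length(object@familyLOD)))
  print(round(object@familyLOD, 4))
})
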