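# Structural model fitting: maximum likelihood over transformed parameters
# (variance proportions through a logistic/softmax map, correlations through
# atanh, thresholds free), quasi-Newton with random restarts.

.family_components <- function(family) {
  base <- sub("-s$", "", family)
  comps <- switch(base,
                  "ACE" = c("A", "C"), "ADE" = c("A", "D"),
                  "AE" = "A", "CE" = "C", "E" = character(0),
                  stop("unknown model family: ", family))
  list(comps = comps, sib = grepl("-s$", family))
}

# Parameter map: list of free-parameter names plus encode/decode closures.
.make_parmap <- function(family, fixed = list(), sex_thresholds = TRUE,
                         free_scale = FALSE) {
  fc <- .family_components(family)
  comps <- fc$comps
  vnames <- unlist(lapply(comps, function(k)
    paste0(tolower(k), "2.", c("trait", "liab"))))
  rnames <- paste0("r", c(comps, "E"))
  snames <- if (fc$sib) c("s.trait", "s.liab") else character(0)
  tnames <- if (sex_thresholds) c("tau.M", "tau.F") else "tau"
  mnames <- if (free_scale) c("mu.trait", "log_sd.trait") else character(0)
  all_names <- c(vnames, rnames, snames, tnames, mnames)
  free <- setdiff(all_names, names(fixed))

  decode <- function(theta) {
    names(theta) <- free
    val <- function(nm, default = 0) {
      if (nm %in% names(fixed)) fixed[[nm]]
      else if (nm %in% free) unname(theta[nm])
      else default
    }
    v <- list(trait = c(), liab = c())
    for (ph in c("trait", "liab")) {
      raw <- vapply(comps, function(k) val(paste0(tolower(k), "2.", ph)), 0)
      if (length(raw)) {
        # fixed entries are proportions already; free ones are softmax logits
        isfix <- paste0(tolower(comps), "2.", ph) %in% names(fixed)
        if (any(isfix) && !all(isfix))
          stop("mixed fixed/free variance components within a phenotype unsupported")
        if (all(isfix)) {
          props <- raw
        } else {
          z <- exp(pmin(raw, 30))
          props <- z / (1 + sum(z))
        }
      } else props <- numeric(0)
      v[[ph]] <- setNames(props, comps)
    }
    rho <- vapply(rnames, function(nm)
      if (nm %in% names(fixed)) fixed[[nm]] else tanh(val(nm)), 0)
    names(rho) <- sub("^r", "", rnames)
    s <- if (fc$sib)
      vapply(snames, function(nm)
        if (nm %in% names(fixed)) fixed[[nm]] else tanh(val(nm)), 0)
    else c(0, 0)
    tau <- if (sex_thresholds) c(M = val("tau.M", 2), F = val("tau.F", 2))
           else { tv <- val("tau", 2); c(M = tv, F = tv) }
    getv <- function(k, ph) if (k %in% comps) v[[ph]][[k]] else 0
    spec <- twin_spec(a2 = c(getv("A", "trait"), getv("A", "liab")),
                      c2 = c(getv("C", "trait"), getv("C", "liab")),
                      d2 = c(getv("D", "trait"), getv("D", "liab")),
                      rA = if ("A" %in% names(rho)) rho[["A"]] else 0,
                      rC = if ("C" %in% names(rho)) rho[["C"]] else 0,
                      rD = if ("D" %in% names(rho)) rho[["D"]] else 0,
                      rE = rho[["E"]],
                      s = unname(s), tau = tau)
    list(spec = spec,
         mu = if (free_scale) val("mu.trait") else 0,
         log_sd = if (free_scale) val("log_sd.trait") else 0)
  }

  encode <- function(start) {
    # start: named list with proportions/correlations on natural scale
    theta <- numeric(0)
    for (nm in free) {
      x <- start[[nm]]
      if (is.null(x)) x <- switch(substr(nm, 1, 2),
                                  "ta" = 2.2, "mu" = 0, "lo" = 0, 0.1)
      th <- if (grepl("^[acde]2\\.", nm)) {
        # invert softmax assuming remaining mass is E
        ph <- sub("^.*\\.", "", nm)
        tot <- sum(vapply(comps, function(k) {
          y <- start[[paste0(tolower(k), "2.", ph)]]
          if (is.null(y)) 0.1 else y
        }, 0))
        e2 <- max(1 - tot, 0.05)
        log(max(x, 1e-3) / e2)
      } else if (grepl("^r|^s\\.", nm)) atanh(max(min(x, 0.99), -0.99))
      else x
      theta <- c(theta, th)
    }
    setNames(theta, free)
  }

  list(free = free, decode = decode, encode = encode, comps = comps,
       sib = fc$sib, sex_thresholds = sex_thresholds, free_scale = free_scale)
}

.negloglik_factory <- function(pm, dat) {
  function(theta) {
    dec <- tryCatch(pm$decode(theta), error = function(e) NULL)
    if (is.null(dec)) return(1e10)
    ll <- 0
    tauv <- c(dec$spec$tau[["M"]], dec$spec$tau[["F"]])
    for (z in names(dat)) {
      R <- tryCatch(cov2cor(implied_moments(dec$spec, z)),
                    error = function(e) NULL)
      if (is.null(R)) return(1e10)
      d <- dat[[z]]
      if (pm$free_scale) {
        sdv <- exp(dec$log_sd)
        d <- modifyList(d, list(t1 = (d$t1 - dec$mu) / sdv,
                                t2 = (d$t2 - dec$mu) / sdv))
      }
      lz <- tryCatch(
        suppressWarnings(.class_loglik(R, d, tauv, log_sd_t = dec$log_sd)),
        error = function(e) NA_real_)  # near-singular R
      if (!is.finite(lz)) return(1e10)
      ll <- ll + lz
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# crude moment-based starting values from the data
.start_values <- function(dat, comps, sib) {
  r_t <- function(z) {
    d <- dat[[z]]
    if (is.null(d)) return(NA_real_)
    ok <- !is.na(d$t1) & !is.na(d$t2)
    if (sum(ok) < 10) return(NA_real_)
    cor(c(d$t1[ok], d$t2[ok]), c(d$t2[ok], d$t1[ok]))
  }
  rmz <- r_t("MZ"); rdz <- r_t("DZ")
  a2t <- if (!is.na(rmz) && !is.na(rdz)) min(max(2 * (rmz - rdz), 0.1), 0.9) else 0.5
  y_all <- unlist(lapply(dat, function(d) c(d$y1, d$y2)))
  prev <- mean(y_all, na.rm = TRUE)
  tau0 <- if (is.finite(prev) && prev > 0 && prev < 1) qnorm(1 - prev) else 2
  t_all <- unlist(lapply(dat, function(d) c(d$t1, d$t2)))
  st <- list(tau.M = tau0, tau.F = tau0, tau = tau0, rE = 0.2,
             s.trait = 0.05, s.liab = 0.05,
             mu.trait = mean(t_all, na.rm = TRUE),
             log_sd.trait = log(max(sd(t_all, na.rm = TRUE), 1e-3)))
  if ("A" %in% comps) { st$a2.trait <- a2t; st$a2.liab <- 0.7; st$rA <- 0.4 }
  if ("C" %in% comps) { st$c2.trait <- 0.1; st$c2.liab <- 0.1; st$rC <- 0.2 }
  if ("D" %in% comps) { st$d2.trait <- 0.1; st$d2.liab <- 0.1; st$rD <- 0.2 }
  st
}

#' Fit a bivariate liability-threshold twin model by maximum likelihood
#'
#' Fits the joint categorical/continuous twin model for one continuous trait
#' and one binary diagnosis. Variance in each phenotype is decomposed
#' according to `family` (`"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`, with an
#' `"-s"` suffix adding reciprocal sibling-interaction paths), correlations
#' between corresponding latent factors are estimated, and diagnoses are
#' linked to a normal liability through sex-specific thresholds. MZ pairs are
#' pooled across sexes and all DZ pairs (same-sex and opposite-sex) share
#' structural parameters; sex enters through the thresholds and the trait
#' standardisation only.
#'
#' Optimisation runs a quasi-Newton search on transformed parameters
#' (softmax for variance proportions, `atanh` for correlations) from a
#' moment-based start plus `restarts - 1` jittered restarts; the best
#' converged solution is kept.
#'
#' @param pairs a [phenotype_table()]
#' @param trait,diagnosis column names of the pairing
#' @param family model family string
#' @param fixed named list pinning parameters (e.g. `list(rA = 0)`); fixed
#'   variance components are given as proportions
#' @param standardize standardise the trait by sex before fitting (the
#'   default); with `FALSE` the trait mean and SD become free parameters
#' @param restarts number of optimiser starts
#' @param seed seed for the restart jitter (does not touch the global RNG
#'   stream's state on exit)
#' @param start optional named list of natural-scale starting values
#'   (e.g. the estimates of a nested fit) merged over the moment-based
#'   defaults
#' @return an object of class `twin_fit`
#' @export
fit_structural <- function(pairs, trait, diagnosis, family = "ACE",
                           fixed = list(), standardize = TRUE,
                           restarts = 5L, seed = 1L, start = NULL) {
  stopifnot(inherits(pairs, "phenotype_table"))
  pt <- pairs
  if (standardize)
    pt[[trait]] <- standardize_by_sex(pt[[trait]], pt$sex)
  dat <- .fit_data(pt, trait, diagnosis)
  if (!length(dat)) stop("no usable pairs")
  pm <- .make_parmap(family, fixed, sex_thresholds = TRUE,
                     free_scale = !standardize)
  nll <- .negloglik_factory(pm, dat)
  st <- .start_values(dat, pm$comps, pm$sib)
  if (!is.null(start)) st <- modifyList(st, start)
  theta0 <- pm$encode(st)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, paste0("fit:", family)))
  best <- NULL
  for (i in seq_len(max(1L, restarts))) {
    th <- if (i == 1L) theta0 else theta0 + rnorm(length(theta0), sd = 0.4)
    o <- tryCatch(
      optim(th, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) next
    # simplex polish guards against quasi-Newton stalls on flat regions
    o2 <- tryCatch(
      optim(o$par, nll, method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o2) && o2$value < o$value) {
      o3 <- tryCatch(
        optim(o2$par, nll, method = "BFGS",
              control = list(maxit = 200, reltol = 1e-12)),
        error = function(e) NULL)
      o <- if (!is.null(o3) && o3$value < o2$value) o3 else o2
    }
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (is.null(best))
    stop("optimisation failed to produce any converged fit for family ", family)

  dec <- pm$decode(best$par)
  spec <- dec$spec
  npar <- length(pm$free)
  N <- sum(vapply(dat, `[[`, 0, "n"))
  loglik <- -best$value
  est <- .collect_estimates(spec, pm, dec)
  fit <- structure(list(
    family = family, spec = spec, estimates = est,
    free = pm$free, fixed = fixed,
    loglik = loglik, npar = npar, N = N,
    BIC = -2 * loglik + npar * log(N),
    convergence = best$convergence,
    theta = best$par, parmap = pm, data = dat,
    trait = trait, diagnosis = diagnosis,
    standardize = standardize, seed = seed,
    boundary = .boundary_flags(spec)),
    class = "twin_fit")
  fit$derived <- .derived_quantities(fit)
  fit
}

.collect_estimates <- function(spec, pm, dec) {
  est <- c(a2.trait = spec$a2[1], a2.liab = spec$a2[2],
           c2.trait = spec$c2[1], c2.liab = spec$c2[2],
           d2.trait = spec$d2[1], d2.liab = spec$d2[2],
           e2.trait = spec$e2[1], e2.liab = spec$e2[2],
           rA = spec$rA, rC = spec$rC, rD = spec$rD, rE = spec$rE,
           s.trait = spec$s[1], s.liab = spec$s[2],
           tau.M = unname(spec$tau["M"]), tau.F = unname(spec$tau["F"]))
  if (pm$free_scale) est <- c(est, mu.trait = dec$mu, sd.trait = exp(dec$log_sd))
  est
}

.boundary_flags <- function(spec, eps = 1e-3) {
  v <- c(a2.trait = spec$a2[1], a2.liab = spec$a2[2],
         c2.trait = spec$c2[1], c2.liab = spec$c2[2],
         d2.trait = spec$d2[1], d2.liab = spec$d2[2])
  r <- c(rA = spec$rA, rC = spec$rC, rD = spec$rD, rE = spec$rE)
  c(names(v)[v > 0 & (v < eps | v > 1 - eps)], names(r)[abs(r) > 1 - eps])
}

# Derived summaries: genetic correlation (for ADE the A+D composite and rA
# are both reported), model-implied phenotypic correlation and its
# decomposition into per-component shares. With sibling interaction the
# shares come from propagating each latent component separately through
# (I - B)^-1 Sigma_k (I - B)^-T, which is exact by linearity.
.derived_quantities <- function(fit) {
  spec <- fit$spec
  comps <- c("A", "D", "C", "E")
  v <- rbind(A = spec$a2, D = spec$d2, C = spec$c2, E = spec$e2)
  r <- c(A = spec$rA, D = spec$rD, C = spec$rC, E = spec$rE)
  B <- matrix(0, 4, 4)
  B[1, 3] <- B[3, 1] <- spec$s[1]
  B[2, 4] <- B[4, 2] <- spec$s[2]
  inv <- solve(diag(4) - B)
  cc <- .cross_coef("MZ")  # within-person covariance is zygosity-free
  obs_k <- lapply(comps, function(k) {
    w <- matrix(c(v[k, 1], r[k] * sqrt(v[k, 1] * v[k, 2]),
                  r[k] * sqrt(v[k, 1] * v[k, 2]), v[k, 2]), 2, 2)
    S <- rbind(cbind(w, cc[k] * w), cbind(cc[k] * w, w))
    inv %*% S %*% t(inv)
  })
  names(obs_k) <- comps
  total <- Reduce(`+`, obs_k)
  sds <- sqrt(diag(total))
  rPh <- total[1, 2] / (sds[1] * sds[2])
  terms <- vapply(obs_k, function(S) S[1, 2] / (sds[1] * sds[2]), 0)
  shares <- if (abs(rPh) > 1e-10) terms / rPh else rep(NA_real_, 4)
  names(shares) <- comps
  gen_var <- v["A", ] + v["D", ]
  rG_comp <- if (all(gen_var > 0))
    (r["A"] * sqrt(v["A", 1] * v["A", 2]) + r["D"] * sqrt(v["D", 1] * v["D", 2])) /
      sqrt(gen_var[1] * gen_var[2])
  else NA_real_
  list(rPh = rPh, rA = unname(r["A"]), rE = unname(r["E"]),
       rG = unname(if (any(v["D", ] > 0)) rG_comp else r["A"]),
       rG_composite = unname(rG_comp),
       shares = shares,
       genetic_share = unname(sum(shares[c("A", "D")], na.rm = TRUE)))
}
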