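#' @include AllClasses.R AllGenerics.R
NULL

# local equirectangular projection (km); equals great-circle distance to
# first order at regional scale
projectKm <- function(lat, lon) {
  kmPerDeg <- 111.32
  data.frame(xkm = kmPerDeg * lon * cos(mean(lat) * pi / 180),
             ykm = kmPerDeg * lat)
}

# name the most collinear predictor pair when the design is singular
# (including collinearity through the intercept)
checkCollinear <- function(X) {
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    cors <- abs(stats::cor(X))
    diag(cors) <- 0
    idx <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    stop(sprintf("collinear predictors: '%s' and '%s'",
                 colnames(X)[idx[1]], colnames(X)[idx[2]]))
  }
  invisible(TRUE)
}

# fixed-effect covariance (X' V^-1 X)^-1 for a random-intercept model,
# from the fitted variance components; equals lme4's RX-based vcov but is
# well defined at zero residual variance (exact fits)
fixefSE <- function(X, group, sigma2, tau2) {
  if (sigma2 < 1e-12) return(rep(0, ncol(X)))
  A <- matrix(0, ncol(X), ncol(X))
  for (g in levels(group)) {
    Xg <- X[group == g, , drop = FALSE]
    cg <- tau2 / (sigma2 + nrow(Xg) * tau2)
    cs <- colSums(Xg)
    A <- A + (crossprod(Xg) - cg * tcrossprod(cs)) / sigma2
  }
  sqrt(diag(solve(A)))
}

#' Mixed-model decomposition of functional dispersion
#'
#' Fits `Q ~ S + J + FRic` with a random year intercept (maximum
#' likelihood, so nested fits are comparable), decomposing functional
#' dispersion into contributions of species richness, evenness and
#' functional richness. With `spatial = TRUE` the residuals additionally
#' carry an exponential spatial correlation declining with great-circle
#' distance between stations, nested within region and year (range
#' estimated; fitted with `nlme`). With fewer than 3 year levels the model
#' degrades to a fixed-intercept linear model with a warning. P-values are
#' Wald z on the fixed effects; `r2` is the squared correlation between
#' fitted and observed responses.
#'
#' @param table data.frame with columns `Q`, `S`, `J`, `FRic`, `year`,
#'   `region`, `lat`, `lon` (as produced by [computeDiversity()]).
#' @param scope `"all"` or a region label to subset to.
#' @param spatial switch on the spatial correlation structure (default
#'   `FALSE`).
#' @return A \linkS4class{DispersionFit}.
#' @export
fitDispersionModel <- function(table, scope = "all", spatial = FALSE) {
  need <- c("Q", "S", "J", "FRic", "year", "region", "lat", "lon")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  df <- if (identical(scope, "all")) table else table[table$region == scope, ]
  df <- as.data.frame(df)
  if (anyNA(df[need])) stop("missing values in model inputs")
  if (nrow(df) < 10) stop("need at least 10 stations (got ", nrow(df), ")")
  nYears <- length(unique(df$year))
  if (nYears < 3) {
    warning("fewer than 3 year levels: fitting a fixed-intercept model")
    checkCollinear(as.matrix(df[, c("S", "J", "FRic")]))
    fit <- stats::lm(Q ~ S + J + FRic, data = df)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], z = sm[, 1] / sm[, 2],
                        p = 2 * stats::pnorm(-abs(sm[, 1] / sm[, 2])),
                        stringsAsFactors = FALSE)
    fitted <- stats::fitted(fit)
    yearVar <- NA_real_
    residVar <- summary(fit)$sigma^2
  } else {
    checkCollinear(as.matrix(df[, c("S", "J", "FRic")]))
    df$yearF <- factor(df$year)
    if (spatial) {
      km <- projectKm(df$lat, df$lon)
      df$xkm <- km$xkm + seq_len(nrow(df)) * 1e-9  # corExp needs distinct positions
      df$ykm <- km$ykm
      fit <- nlme::lme(Q ~ S + J + FRic, random = ~ 1 | yearF,
                       correlation = nlme::corExp(form = ~ xkm + ykm | yearF / region),
                       data = df, method = "ML",
                       control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
      tt <- summary(fit)$tTable
      est <- tt[, "Value"]; se <- tt[, "Std.Error"]
      vc <- nlme::VarCorr(fit)
      yearVar <- as.numeric(vc["(Intercept)", "Variance"])
      residVar <- fit$sigma^2
      fitted <- as.numeric(stats::fitted(fit))
    } else {
      fit <- lme4::lmer(Q ~ S + J + FRic + (1 | yearF), data = df,
                        REML = FALSE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
      est <- lme4::fixef(fit)
      vc <- as.data.frame(lme4::VarCorr(fit))
      yearVar <- vc$vcov[vc$grp == "yearF"]
      residVar <- vc$vcov[vc$grp == "Residual"]
      X <- stats::model.matrix(~ S + J + FRic, df)
      se <- fixefSE(X, df$yearF, residVar, yearVar)
      fitted <- as.numeric(stats::fitted(fit))
    }
    z <- est / se
    coefs <- data.frame(term = names(est), estimate = as.numeric(est),
                        se = as.numeric(se), z = as.numeric(z),
                        p = 2 * stats::pnorm(-abs(as.numeric(z))),
                        stringsAsFactors = FALSE)
  }
  coefs$term[coefs$term == "(Intercept)"] <- "intercept"
  r2 <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, df$Q)^2
  new("DispersionFit", coefficients = coefs, r2 = r2,
      yearVariance = yearVar, residVariance = residVar,
      scope = if (identical(scope, "all")) "all" else as.character(scope),
      spatial = spatial, nStations = nrow(df), nYears = as.integer(nYears),
      fitted = as.numeric(fitted), observed = df$Q)
}

#' Region-specific dispersion models
#'
#' Fits [fitDispersionModel()] separately within each region (regions with
#' fewer than 10 stations are skipped with a warning) and reports the
#' per-region variance explained for comparison.
#'
#' @param table as in [fitDispersionModel()].
#' @param spatial passed through.
#' @return A list with `fits` (named list of \linkS4class{DispersionFit})
#'   and `comparison` (data.frame: `region`, `r2`, `n_stations`).
#' @export
regionSpecificFits <- function(table, spatial = FALSE) {
  regions <- sort(unique(table$region))
  fits <- list()
  for (rg in regions) {
    nst <- sum(table$region == rg)
    if (nst < 10) {
      warning(sprintf("region '%s' skipped: only %d stations", rg, nst))
      next
    }
    fits[[rg]] <- fitDispersionModel(table, scope = rg, spatial = spatial)
  }
  comparison <- data.frame(
    region = names(fits),
    r2 = vapply(fits, function(f) f@r2, numeric(1)),
    n_stations = vapply(fits, function(f) f@nStations, integer(1)),
    stringsAsFactors = FALSE)
  rownames(comparison) <- NULL
  list(fits = fits, comparison = comparison)
}

#' Model summary table
#'
#' Flattens one or more \linkS4class{DispersionFit} objects into the
#' long-format summary written by the pipeline.
#'
#' @param ... \linkS4class{DispersionFit} objects.
#' @return data.frame: `scope`, `term`, `estimate`, `se`, `p`, `r2`,
#'   `n_stations`, `n_years`.
#' @export
modelSummaryTable <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !is(fits[[1]], "DispersionFit"))
    fits <- fits[[1]]
  do.call(rbind, lapply(fits, function(f) {
    data.frame(scope = f@scope, term = f@coefficients$term,
               estimate = f@coefficients$estimate, se = f@coefficients$se,
               p = f@coefficients$p, r2 = f@r2, n_stations = f@nStations,
               n_years = f@nYears, stringsAsFactors = FALSE)
  }))
}
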