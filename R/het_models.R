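# Heterozygosity-model module: the ladder of binomial cloglog regressions
# for the probability that a locus is heterozygous, and the derived
# "TE Effect" grouping of superfamilies.
#
# Response: per SNP x relatedness-cluster cell, the heterozygote count out
# of the cell's sample count, modeled with a binomial distribution and
# complementary log-log link. Relatedness enters as fixed cluster
# intercepts by default (few clusters, many observations); a Laplace
# random-intercept fit (glmmTMB) is available. Distance to the nearest TE
# is rescaled to kb and entered with linear and quadratic terms.

#' Build the SNP-by-cluster observation table for heterozygosity models
#'
#' One row per SNP x relatedness cluster with at least one sample in the
#' (optionally subset) sample set: heterozygote count, sample count,
#' nearest-TE covariates, optional selection class and TE-effect group,
#' and the mean F_IS of the cell's samples. SNPs with the no-TE sentinel
#' context are excluded.
#'
#' @param genotable a complete-case `genotype_table`.
#' @param contexts nearest-TE contexts (see [nearest_te()]).
#' @param clusters integer cluster label per sample
#'   ([relatedness_clusters()]).
#' @param fis per-sample F_IS (data.frame from [sample_fis()] or a numeric
#'   vector aligned with samples).
#' @param calls optional selection calls ([classify_selection()]); adds
#'   `selection_class`.
#' @param te_effect_set optional character vector of TE-Effect
#'   superfamilies; adds `te_effect_group` (`H_TE` / `H_0`).
#' @param samples optional subset: logical vector over samples or
#'   character sample ids. Errors if the subset is empty.
#' @return data.frame of model observations.
#' @export
build_observations <- function(genotable, contexts, clusters, fis,
                               calls = NULL, te_effect_set = NULL,
                               samples = NULL) {
  g <- genotable$genotypes
  sam <- genotable$samples
  if (is.data.frame(fis)) fis <- fis$fis[match(sam$sample_id, fis$sample_id)]
  keep <- rep(TRUE, nrow(g))
  if (!is.null(samples)) {
    keep <- if (is.character(samples)) sam$sample_id %in% samples
            else as.logical(samples)
  }
  if (!any(keep)) stop("sample subset is empty")
  ctx <- contexts[match(genotable$snps$snp_id, contexts$snp_id), ]
  snp_keep <- ctx$te_id != NO_TE_SENTINEL
  if (!any(snp_keep)) stop("no SNPs with a TE context")

  cl <- clusters[match(sam$sample_id, names(clusters))]
  if (anyNA(cl)) cl <- unname(clusters)   # positional fallback
  ucl <- sort(unique(cl[keep]))
  blocks <- lapply(ucl, function(cc) {
    rows <- keep & cl == cc
    if (!any(rows)) return(NULL)
    data.frame(snp_id = genotable$snps$snp_id[snp_keep],
               cluster_id = cc,
               het_count = colSums(g[rows, snp_keep, drop = FALSE] == 1),
               n_samples = sum(rows),
               superfamily = ctx$superfamily[snp_keep],
               sense = ctx$sense[snp_keep],
               distance_bp = ctx$distance_bp[snp_keep],
               mean_fis = mean(fis[rows], na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, blocks)
  obs$distance_kb <- obs$distance_bp / 1000
  obs$distance_kb2 <- obs$distance_kb^2
  obs$sense <- factor(obs$sense, levels = c("upstream", "downstream", "within"))
  if (!is.null(te_effect_set))
    obs$te_effect_group <- factor(
      ifelse(obs$superfamily %in% te_effect_set, "H_TE", "H_0"),
      levels = c("H_0", "H_TE"))
  if (!is.null(calls))
    obs$selection_class <- factor(
      calls$class[match(obs$snp_id, calls$snp_id)],
      levels = c("neutral", "balancing", "divergent"))
  obs
}

# log-likelihood, mu and IRLS weights of a binomial cloglog model
cloglog_mu <- function(eta) pmin(pmax(-expm1(-exp(eta)), 1e-12), 1 - 1e-12)

cloglog_loglik <- function(beta, X, y, n) {
  mu <- cloglog_mu(drop(X %*% beta))
  sum(y * log(mu) + (n - y) * log(1 - mu))
}

cloglog_weights <- function(beta, X, n) {
  eta <- drop(X %*% beta)
  mu <- cloglog_mu(eta)
  dmu <- exp(eta - exp(eta))
  n * dmu^2 / (mu * (1 - mu))
}

# Firth-style fit: maximize loglik + 0.5 log det(X'WX) (Jeffreys penalty)
firth_cloglog <- function(X, y, n, start) {
  pen <- function(beta) {
    w <- cloglog_weights(beta, X, n)
    info <- crossprod(X * sqrt(w))
    ld <- determinant(info, logarithm = TRUE)
    -(cloglog_loglik(beta, X, y, n) + 0.5 * as.numeric(ld$modulus))
  }
  opt <- optim(start, pen, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par
  info <- crossprod(X * sqrt(cloglog_weights(beta, X, n)))
  list(coefficients = beta, vcov = solve(info))
}

#' Fit a binomial cloglog model for heterozygosity
#'
#' Fits `cbind(het_count, n_samples - het_count) ~ <terms>` with a
#' binomial family and complementary log-log link by iteratively
#' reweighted least squares (relative deviance change below 1e-8, at most
#' 100 iterations). Relatedness clusters enter as fixed intercepts
#' (default) or as a Laplace-approximated random intercept (glmmTMB).
#' Aliased (rank-deficient) columns are dropped and reported. Apparent
#' separation (any coefficient beyond 15 on the linear scale) triggers a
#' warning and a Firth-style (Jeffreys-penalized) refit.
#'
#' @param observations table from [build_observations()].
#' @param formula_terms character right-hand side, e.g.
#'   `"distance_kb * te_effect_group + sense"` (do not include the
#'   cluster term; it is added according to `cluster_handling`).
#' @param cluster_handling `"fixed"` or `"random"`.
#' @return object of class `het_model_fit`: list with `fit`,
#'   `coefficients` (term / estimate / se / z / p), `anodev` (type-II
#'   analysis of deviance), `aliased`, `separation`, `meta`.
#' @export
fit_cloglog_binomial <- function(observations,
                                 formula_terms,
                                 cluster_handling = c("fixed", "random")) {
  cluster_handling <- match.arg(cluster_handling)
  obs <- droplevels(observations)
  multi_cluster <- length(unique(obs$cluster_id)) > 1
  if (cluster_handling == "fixed") {
    rhs <- if (multi_cluster)
      paste(formula_terms, "+ factor(cluster_id)") else formula_terms
    form <- as.formula(paste("cbind(het_count, n_samples - het_count) ~", rhs))
    fit <- glm(form, family = binomial(link = "cloglog"), data = obs,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    cf <- summary(fit)$coefficients
    aliased <- names(which(is.na(coef(fit))))
    est <- setNames(cf[, 1], rownames(cf))
    se <- setNames(cf[, 2], rownames(cf))
  } else {
    rhs <- if (multi_cluster)
      paste(formula_terms, "+ (1 | cluster_id)") else formula_terms
    form <- as.formula(paste("cbind(het_count, n_samples - het_count) ~", rhs))
    fit <- glmmTMB::glmmTMB(form, family = binomial(link = "cloglog"),
                            data = obs)
    cf <- summary(fit)$coefficients$cond
    aliased <- character()
    est <- setNames(cf[, 1], rownames(cf))
    se <- setNames(cf[, 2], rownames(cf))
  }
  separation <- any(abs(est) > 15, na.rm = TRUE)
  if (separation && cluster_handling == "fixed") {
    warning("possible separation (|coefficient| > 15); ",
            "applying Firth-style penalized refit")
    X <- stats::model.matrix(fit)
    ok <- !is.na(coef(fit))
    ff <- firth_cloglog(X[, ok, drop = FALSE], obs$het_count, obs$n_samples,
                        start = ifelse(abs(coef(fit)[ok]) > 15, 0,
                                       coef(fit)[ok]))
    est <- ff$coefficients
    se <- sqrt(diag(ff$vcov))
    names(est) <- names(se) <- colnames(X)[ok]
  }
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  anodev <- if (trimws(formula_terms) == "1") NULL else tryCatch({
    a <- if (inherits(fit, "glmmTMB")) car::Anova(fit, type = "II")
         else car::Anova(fit, type = "II", test.statistic = "LR")
    data.frame(term = rownames(a), statistic = a[, 1], df = a[, 2],
               p = a[, ncol(a)], row.names = NULL, stringsAsFactors = FALSE)
  }, error = function(e) NULL)
  structure(list(fit = fit, coefficients = coefs, anodev = anodev,
                 aliased = aliased, separation = separation,
                 meta = list(link = "cloglog", terms = formula_terms,
                             cluster_handling = cluster_handling,
                             n_obs = nrow(obs))),
            class = "het_model_fit")
}

#' @export
print.het_model_fit <- function(x, ...) {
  cat(sprintf("binomial cloglog fit (%s clusters), %d observations\n",
              x$meta$cluster_handling, x$meta$n_obs))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# contrasts of each (superfamily, sense) cell against the reference
# superfamily within the same sense, from a fit on the combo factor
# `sf_sense` (dummy coding, some reference combo level)
superfamily_sense_contrasts <- function(hfit, reference = "CACTA") {
  fit <- hfit$fit
  beta <- coef(fit)
  V <- vcov(fit)
  ok <- !is.na(beta)
  beta <- beta[ok]; V <- V[ok, ok, drop = FALSE]
  lv <- grep("^sf_sense", names(beta), value = TRUE)
  all_levels <- levels(stats::model.frame(fit)$sf_sense)
  cells <- data.frame(level = all_levels, stringsAsFactors = FALSE)
  parts <- strsplit(cells$level, "||", fixed = TRUE)
  cells$superfamily <- vapply(parts, `[`, "", 1)
  cells$sense <- vapply(parts, `[`, "", 2)
  cells$coefname <- paste0("sf_sense", cells$level)
  cells$present <- cells$coefname %in% names(beta) |
    cells$level == all_levels[1]
  out <- NULL
  for (s in unique(cells$sense)) {
    ref_row <- cells[cells$superfamily == reference & cells$sense == s, ]
    if (nrow(ref_row) != 1 || !ref_row$present) next
    for (i in which(cells$sense == s & cells$superfamily != reference &
                    cells$present)) {
      cvec <- setNames(numeric(length(beta)), names(beta))
      if (cells$coefname[i] %in% names(beta)) cvec[cells$coefname[i]] <- 1
      if (ref_row$coefname %in% names(beta)) cvec[ref_row$coefname] <- -1
      est <- sum(cvec * beta)
      sev <- sqrt(drop(t(cvec) %*% V %*% cvec))
      out <- rbind(out, data.frame(
        superfamily = cells$superfamily[i], sense = s,
        estimate = est, se = sev, z = est / sev,
        p = 2 * pnorm(-abs(est / sev)), stringsAsFactors = FALSE))
    }
  }
  out
}

# add the superfamily-by-sense combo factor, reference superfamily first
add_sf_sense <- function(obs, reference = "CACTA") {
  combo <- paste(obs$superfamily, obs$sense, sep = "||")
  ref_levels <- sort(unique(combo))
  ref_first <- c(grep(paste0("^", reference, "\\|\\|"), ref_levels, value = TRUE),
                 setdiff(ref_levels, grep(paste0("^", reference, "\\|\\|"),
                                          ref_levels, value = TRUE)))
  obs$sf_sense <- factor(combo, levels = ref_first)
  obs
}

#' The exploratory Model 0 pair and the derived TE-Effect superfamily set
#'
#' Fits the exploratory heterozygosity model `H ~ superfamily:sense +
#' distance (+ distance^2)` on the highly inbred sample subset (Model 0a)
#' and on the remaining samples (Model 0b), then derives the TE-Effect
#' grouping in three steps: (1) a type-II analysis-of-deviance gate on the
#' superfamily-by-sense term in Model 0a (if not significant at
#' `p_threshold` the set is empty); (2) a superfamily is a candidate when
#' its downstream-sense contrast against the reference superfamily is
#' significantly positive in Model 0a (elevated heterozygosity under
#' inbreeding); (3) the candidate's elevation must be inbreeding
#' dependent: the 0a-minus-0b interaction contrast (same SNPs in both
#' subsets, so between-SNP allele-frequency composition cancels) must be
#' significantly positive. Superfamilies elevated in both subsets alike
#' (the LINE pattern) fail step 3 and are excluded.
#'
#' @param obs0a,obs0b observation tables ([build_observations()]) for the
#'   inbred and outcrossed subsets.
#' @param p_threshold Wald significance level (default 0.05, uncorrected).
#' @param reference reference superfamily for contrasts (default
#'   `"CACTA"`; falls back to the first present superfamily).
#' @param cluster_handling passed to [fit_cloglog_binomial()].
#' @return list: `fit0a`, `fit0b`, `te_effect_set`, `evidence`
#'   (per-superfamily contrast table), `gate_p`.
#' @export
model0_te_effect <- function(obs0a, obs0b, p_threshold = 0.05,
                             reference = "CACTA",
                             cluster_handling = "fixed") {
  if (!reference %in% obs0a$superfamily)
    reference <- sort(unique(obs0a$superfamily))[1]
  obs0a <- add_sf_sense(obs0a, reference)
  obs0b <- add_sf_sense(obs0b, reference)
  fit0a <- fit_cloglog_binomial(obs0a, "sf_sense + distance_kb + distance_kb2",
                                cluster_handling)
  fit0b <- fit_cloglog_binomial(obs0b, "sf_sense + distance_kb + distance_kb2",
                                cluster_handling)
  gate_p <- NA_real_
  if (!is.null(fit0a$anodev)) {
    row <- fit0a$anodev$term == "sf_sense"
    if (any(row)) gate_p <- fit0a$anodev$p[row][1]
  }
  con_a <- superfamily_sense_contrasts(fit0a, reference)
  con_b <- superfamily_sense_contrasts(fit0b, reference)
  set <- character()
  interaction_tab <- NULL
  if (!is.na(gate_p) && gate_p < p_threshold && !is.null(con_a)) {
    down_a <- con_a[con_a$sense == "downstream", ]
    cand <- down_a$superfamily[down_a$estimate > 0 & down_a$p < p_threshold]
    # inbreeding dependence: the same SNPs underlie the 0a and 0b cells,
    # so the 0a-minus-0b interaction contrast cancels between-SNP
    # allele-frequency composition; a superfamily must be elevated
    # significantly MORE under inbreeding than without it (the LINE
    # pattern, elevated in both subsets alike, is excluded here)
    if (!is.null(con_b)) {
      down_b <- con_b[con_b$sense == "downstream", ]
      m <- merge(down_a, down_b, by = "superfamily",
                 suffixes = c("_a", "_b"))
      m$est_int <- m$estimate_a - m$estimate_b
      m$se_int <- sqrt(m$se_a^2 + m$se_b^2)
      m$z_int <- m$est_int / m$se_int
      m$p_int <- 2 * pnorm(-abs(m$z_int))
      interaction_tab <- m[, c("superfamily", "est_int", "se_int",
                               "z_int", "p_int")]
      dep <- m$superfamily[m$est_int > 0 & m$p_int < p_threshold]
      cand <- intersect(cand, union(dep,
                                    setdiff(cand, m$superfamily)))
    }
    set <- sort(cand)
  }
  ev_a <- if (!is.null(con_a)) cbind(model = "0a", con_a) else NULL
  ev_b <- if (!is.null(con_b)) cbind(model = "0b", con_b) else NULL
  list(fit0a = fit0a, fit0b = fit0b, te_effect_set = set,
       evidence = rbind(ev_a, ev_b), interaction = interaction_tab,
       gate_p = gate_p)
}

#' Fit the full ladder of heterozygosity models
#'
#' Runs Models 0a/0b on the inbred (`F_IS > fis_split`) vs outcrossed
#' sample subsets, derives the TE-Effect grouping, and fits: Model 1
#' (`H ~ Distance x TE Effect + TE Effect x Sense + Distance x Sense`, all
#' samples), Models 2a/2b (`H ~ F_IS x Selection + Sense x Selection` on
#' the H_TE and H_0 SNP subsets), and, when a second-lineage dataset is
#' supplied, Model 3 (`H ~ TE Effect + Sense`) on its two F_IS subsets
#' (above and below `fis_split_europe`). If the TE-Effect set is empty,
#' Models 2a and 3 are skipped and reported as such.
#'
#' @param genotable,contexts,clusters,fis,calls primary-lineage inputs
#'   (see [build_observations()]).
#' @param fis_split F_IS split between inbred and outcrossed samples
#'   (default 0.6).
#' @param europe optional list with elements `genotable`, `contexts`,
#'   `clusters`, `fis` for the independent outcrossing lineage.
#' @param fis_split_europe F_IS split within the outcrossing lineage
#'   (default -0.3).
#' @param p_threshold significance level for TE-Effect membership.
#' @param reference reference superfamily (default `"CACTA"`).
#' @param cluster_handling `"fixed"` or `"random"`.
#' @return list: `fits` (named list of `het_model_fit`; models `0a`, `0b`,
#'   `1`, `2a`, `2b`, `3_high_fis`, `3_low_fis` as available),
#'   `te_effect_set`, `te_effect_evidence`, `gate_p`, `skipped` (named
#'   character vector of skip reasons).
#' @export
model_ladder <- function(genotable, contexts, clusters, fis, calls = NULL,
                         fis_split = 0.6, europe = NULL,
                         fis_split_europe = -0.3, p_threshold = 0.05,
                         reference = "CACTA", cluster_handling = "fixed") {
  if (is.data.frame(fis))
    fisv <- fis$fis[match(genotable$samples$sample_id, fis$sample_id)]
  else fisv <- fis
  inbred <- !is.na(fisv) & fisv > fis_split
  outx <- !is.na(fisv) & fisv <= fis_split
  if (!any(inbred)) stop("no samples with F_IS above the inbred split")
  if (!any(outx)) stop("no samples at or below the inbred split")
  obs0a <- build_observations(genotable, contexts, clusters, fis,
                              samples = inbred)
  obs0b <- build_observations(genotable, contexts, clusters, fis,
                              samples = outx)
  m0 <- model0_te_effect(obs0a, obs0b, p_threshold, reference,
                         cluster_handling)
  set <- m0$te_effect_set
  fits <- list(`0a` = m0$fit0a, `0b` = m0$fit0b)
  skipped <- character()

  obs_all <- build_observations(genotable, contexts, clusters, fis,
                                calls = calls,
                                te_effect_set = set)
  if (length(set) > 0 && nlevels(droplevels(obs_all$te_effect_group)) > 1) {
    fits$`1` <- fit_cloglog_binomial(
      obs_all,
      "(distance_kb + distance_kb2) * te_effect_group + te_effect_group * sense + (distance_kb + distance_kb2) * sense",
      cluster_handling)
  } else {
    fits$`1` <- fit_cloglog_binomial(
      obs_all, "(distance_kb + distance_kb2) * sense", cluster_handling)
    skipped["1_te_effect_terms"] <- "TE-Effect set empty; Model 1 fitted without TE-Effect terms"
  }

  model2_terms <- function(obs2) {
    # drop factor terms that are constant within the subset
    sel_ok <- length(unique(obs2$selection_class[!is.na(obs2$selection_class)])) > 1
    sense_ok <- length(unique(obs2$sense)) > 1
    if (sel_ok && sense_ok) "mean_fis * selection_class + sense * selection_class"
    else if (sel_ok) "mean_fis * selection_class"
    else if (sense_ok) "mean_fis + sense"
    else "mean_fis"
  }
  if (!is.null(calls)) {
    if (length(set) > 0) {
      obs2a <- obs_all[obs_all$te_effect_group == "H_TE", ]
      fits$`2a` <- fit_cloglog_binomial(obs2a, model2_terms(obs2a),
                                        cluster_handling)
    } else {
      skipped["2a"] <- "TE-Effect set empty"
    }
    obs2b <- obs_all[obs_all$te_effect_group %in% "H_0" |
                       length(set) == 0, ]
    fits$`2b` <- fit_cloglog_binomial(obs2b, model2_terms(obs2b),
                                      cluster_handling)
  } else {
    skipped["2a"] <- skipped["2b"] <- "no selection calls supplied"
  }

  if (!is.null(europe)) {
    if (length(set) > 0) {
      efisv <- if (is.data.frame(europe$fis))
        europe$fis$fis[match(europe$genotable$samples$sample_id,
                             europe$fis$sample_id)]
      else europe$fis
      for (side in c("high", "low")) {
        sel <- if (side == "high") !is.na(efisv) & efisv > fis_split_europe
               else !is.na(efisv) & efisv <= fis_split_europe
        key <- paste0("3_", side, "_fis")
        if (!any(sel)) { skipped[key] <- "empty F_IS subset"; next }
        obs3 <- build_observations(europe$genotable, europe$contexts,
                                   europe$clusters, europe$fis,
                                   te_effect_set = set, samples = sel)
        if (nlevels(droplevels(obs3$te_effect_group)) < 2) {
          skipped[key] <- "TE-Effect group constant in subset"; next
        }
        fits[[key]] <- fit_cloglog_binomial(obs3, "te_effect_group + sense",
                                            cluster_handling)
      }
    } else {
      skipped["3"] <- "TE-Effect set empty"
    }
  }

  list(fits = fits, te_effect_set = set,
       te_effect_evidence = m0$evidence, gate_p = m0$gate_p,
       skipped = skipped)
}
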