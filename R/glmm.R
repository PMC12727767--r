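#' Binomial-logit mixed model for group-level freezing counts
#'
#' Fits a generalized linear mixed model to the number of freezing
#' individuals (0-6) per group-trial: binomial family with logit link,
#' user-chosen fixed effects (cluster identity and/or familiarisation) and
#' random intercepts (group identity, trial number, optionally experimental
#' group identity). Pairwise contrasts between fixed-effect levels use
#' Tukey's method.
#'
#' Complete separation (a fixed-effect level whose counts are all 0 or all
#' n) and non-convergence are flagged on the returned object rather than
#' raised, so degenerate inputs yield an inspectable result.
#'
#' @param data data.frame with an `fs` column (freezing count per
#'   group-trial) plus the fixed- and random-effect columns.
#' @param fixed Character vector of fixed-effect column names (each with at
#'   least 2 levels).
#' @param random Character vector of random-intercept column names.
#' @param n_individuals Binomial denominator (group size).
#' @return A `group_glmm` list: `coefficients` (fixed effects, log-odds, with
#'   SEs), `contrasts` (Tukey-adjusted pairwise comparisons per fixed
#'   effect), `varcor` (random-effect variances), `converged`, `separation`,
#'   `model` (the `glmerMod` fit or NULL).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_groups = 6, coupling = 0, seed = 2)
#' st <- simulate_states(cfg)$states
#' h <- count_fs_per_trial(st)
#' d <- merge(h$counts, unique(st[, c("group", "archetype")]), by = "group")
#' fit <- fit_group_glmm(d, fixed = "archetype", random = c("group", "trial"))
#' fit$contrasts
#' }
#' @export
fit_group_glmm <- function(data, fixed, random = c("group", "trial"),
                           n_individuals = 6) {
  if (!"fs" %in% names(data)) stop("`data` needs an `fs` count column", call. = FALSE)
  if (any(data$fs < 0 | data$fs > n_individuals)) {
    stop(sprintf("`fs` must lie in 0..%d", n_individuals), call. = FALSE)
  }
  missing_cols <- setdiff(c(fixed, random), names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  for (f in fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L) {
      stop(sprintf("fixed effect `%s` needs at least 2 levels", f), call. = FALSE)
    }
  }
  for (r in random) data[[r]] <- factor(data[[r]])

  # complete-separation screen: any fixed-effect level with all-0 or all-max
  # counts has an infinite log-odds estimate
  separation <- FALSE
  for (f in fixed) {
    for (lev in levels(data[[f]])) {
      v <- data$fs[data[[f]] == lev]
      if (all(v == 0) || all(v == n_individuals)) separation <- TRUE
    }
  }

  fml <- stats::as.formula(paste(
    "cbind(fs, n_ind - fs) ~",
    paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  ))
  data$n_ind <- n_individuals

  converged <- TRUE
  model <- tryCatch(
    withCallingHandlers(
      lme4::glmer(fml, data = data, family = stats::binomial(link = "logit")),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(model)) {
    return(structure(list(coefficients = NULL, contrasts = NULL, varcor = NULL,
                          converged = FALSE, separation = separation, model = NULL),
                     class = "group_glmm"))
  }

  sm <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "z value"],
                      p = sm[, "Pr(>|z|)"], row.names = NULL,
                      stringsAsFactors = FALSE)

  contrasts <- lapply(fixed, function(f) {
    args <- stats::setNames(list("Tukey"), f)
    cmp <- tryCatch(
      summary(multcomp::glht(model, linfct = do.call(multcomp::mcp, args))),
      error = function(e) NULL
    )
    if (is.null(cmp)) return(NULL)
    data.frame(
      effect = f,
      contrast = rownames(cmp$linfct),
      estimate = as.numeric(cmp$test$coefficients),
      se = as.numeric(cmp$test$sigma),
      z = as.numeric(cmp$test$tstat),
      p_tukey = as.numeric(cmp$test$pvalues),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  contrasts <- do.call(rbind, contrasts)

  vc <- lme4::VarCorr(model)
  varcor <- data.frame(
    term = names(vc),
    variance = vapply(vc, function(m) as.numeric(m[1, 1]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(coefficients = coefs, contrasts = contrasts, varcor = varcor,
                 converged = converged, separation = separation, model = model),
            class = "group_glmm")
}

#' @export
print.group_glmm <- function(x, ...) {
  cat("<group_glmm> binomial-logit mixed model\n")
  if (is.null(x$model)) {
    cat("  fit failed")
  } else {
    cat(sprintf("  converged: %s, separation flag: %s\n", x$converged, x$separation))
    print(x$coefficients, digits = 3)
    if (!is.null(x$contrasts)) {
      cat("  Tukey contrasts:\n")
      print(x$contrasts, digits = 3)
    }
  }
  invisible(x)
}
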