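# Bulk-cohort propagation of the lineage signature: per-sample ontogeny
# scores, subtype comparison by Tukey's range test, and median-split Cox
# survival adjusted for age and gender.

#' Score bulk samples with the lineage signature
#'
#' Per sample, the blood and microglia scores are the unweighted means of
#' the available signature genes of each lineage; z-scored variants across
#' the cohort are attached. Signature genes missing from the cohort are
#' reported in the `missing_genes` attribute (an error if none overlap).
#'
#' @param cohort a [bulk_cohort()] object.
#' @param signature a [signature_gene_set()].
#' @return A `data.frame` (class `ontogeny_scores`): `sample_id`,
#'   `blood_score`, `microglia_score`, `blood_z`, `microglia_z`.
#' @export
ontogeny_score <- function(cohort, signature) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(signature, "signature_gene_set"))
  present <- signature$gene %in% colnames(cohort$expr)
  if (!any(present)) {
    stop("no signature gene present in cohort; missing: ",
         paste(utils::head(signature$gene, 10), collapse = ", "))
  }
  missing <- signature$gene[!present]
  if (length(missing)) {
    message(sprintf("%d signature gene(s) absent from cohort", length(missing)))
  }
  sig <- signature[present, , drop = FALSE]
  score_for <- function(lin) {
    g <- sig$gene[sig$lineage == lin]
    if (length(g) == 0) return(rep(NA_real_, nrow(cohort$expr)))
    rowMeans(cohort$expr[, g, drop = FALSE])
  }
  blood <- score_for("blood")
  microglia <- score_for("microglia")
  zs <- function(x) if (all(is.na(x)) || stats::sd(x) == 0) x * NA else as.numeric(scale(x))
  out <- data.frame(sample_id = cohort$clinical$sample_id,
                    blood_score = blood, microglia_score = microglia,
                    blood_z = zs(blood), microglia_z = zs(microglia),
                    stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- missing
  class(out) <- c("ontogeny_scores", "data.frame")
  out
}

#' Compare ontogeny scores across glioma subtypes
#'
#' One-way Tukey honest-significant-difference test of each score over the
#' subtype labels, with adjusted p values from the studentized range
#' distribution.
#'
#' @param scores an [ontogeny_score()] result (or any data frame with
#'   `blood_z` / `microglia_z` columns).
#' @param subtypes subtype label per sample (>= 2 groups with >= 2 samples
#'   each).
#' @return A `data.frame` with columns `score`, `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`.
#' @export
subtype_comparison <- function(scores, subtypes) {
  subtypes <- factor(subtypes)
  if (nlevels(subtypes) < 2) stop("need at least 2 subtype groups")
  if (any(table(subtypes) < 2)) stop("each subtype needs at least 2 samples")
  res <- list()
  for (sc in c("blood_z", "microglia_z")) {
    y <- scores[[sc]]
    if (is.null(y) || all(is.na(y))) next
    fit <- stats::aov(y ~ subtypes)
    tk <- stats::TukeyHSD(fit)$subtypes
    res[[sc]] <- data.frame(score = sub("_z$", "", sc), pair = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split samples at the median score
#'
#' High stratum: strictly above the median; ties at the median go to the
#' low stratum.
#'
#' @param scores numeric vector (>= 2 values).
#' @return Logical vector, `TRUE` for the high stratum.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  if (length(unique(scores)) == 1) stop("all scores identical; no split possible")
  scores > stats::median(scores)
}

#' Cox proportional-hazards survival of a score stratum
#'
#' Fits a proportional-hazards model of the high-vs-low stratum adjusted
#' for covariates, with Efron handling of tied event times. The hazard
#' ratio is for the high stratum relative to the low stratum. Kaplan-Meier
#' curves per stratum are returned as step-function tables.
#'
#' @param cohort a [bulk_cohort()] object.
#' @param strata logical (or two-level) vector from [median_split()].
#' @param covariates clinical columns to adjust for.
#' @return An object of class `tam_cox`: `hr`, `log_hr`, `log_hr_se`, `p`
#'   (Wald), `conf_int` (95% on the HR), `coefficients` (full table), `n`
#'   (samples and events per stratum), `km` (stratum step tables),
#'   `separation` flag.
#' @export
cox_survival <- function(cohort, strata, covariates = c("age", "gender")) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  cl <- cohort$clinical
  strata <- as.logical(strata)
  if (length(strata) != nrow(cl)) stop("strata length must match sample count")
  ev <- tapply(cl$event, strata, sum)
  if (length(ev) < 2 || any(ev == 0)) stop("need at least 1 event per stratum")
  dat <- data.frame(time = cl$time, event = cl$event, high = strata,
                    cl[, intersect(covariates, names(cl)), drop = FALSE])
  miss <- setdiff(covariates, names(cl))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(c("high", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  sm <- summary(fit)
  co <- sm$coefficients
  i <- grep("^high", rownames(co))[1]
  separation <- abs(co[i, "coef"]) > 10 || co[i, "se(coef)"] > 10
  if (separation) warning("possible separation: extreme stratum coefficient")
  km_fit <- survival::survfit(survival::Surv(time, event) ~ high, data = dat)
  km <- data.frame(stratum = rep(sub("high=", "", names(km_fit$strata)),
                                 km_fit$strata),
                   time = km_fit$time, n_risk = km_fit$n.risk,
                   n_event = km_fit$n.event, surv = km_fit$surv,
                   stringsAsFactors = FALSE)
  structure(list(hr = unname(exp(co[i, "coef"])),
                 log_hr = unname(co[i, "coef"]),
                 log_hr_se = unname(co[i, "se(coef)"]),
                 p = unname(co[i, "Pr(>|z|)"]),
                 conf_int = unname(exp(co[i, "coef"] + c(-1, 1) * 1.96 * co[i, "se(coef)"])),
                 coefficients = co,
                 n = table(factor(ifelse(strata, "high", "low"),
                                  levels = c("low", "high"))),
                 n_events = ev,
                 km = km,
                 separation = separation,
                 reference = "low stratum; gender reference = first level"),
            class = "tam_cox")
}

#' @export
print.tam_cox <- function(x, ...) {
  cat(sprintf("<tam_cox> HR (high vs low) = %.3f [%.3f, %.3f], p = %.3g\n",
              x$hr, x$conf_int[1], x$conf_int[2], x$p))
  invisible(x)
}
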