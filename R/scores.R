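#' Default BIMAST coefficients
#'
#' The published linear score: 0.17 per kg/m2 of BMI, 0.054 per IU/L of AST,
#' intercept -8.771.
#' @export
bimast_coefficients <- function() {
  list(intercept = -8.771, beta_bmi = 0.17, beta_ast = 0.054)
}

#' BIMAST score
#'
#' Linear fibrosis screening score for diabetic primary care:
#' `beta_bmi * BMI + beta_ast * AST + intercept`. Strictly increasing in both
#' inputs. Screening positivity is score > 0.063 for significant fibrosis and
#' > 0.102 for advanced fibrosis.
#'
#' @param bmi Body mass index, kg/m2 (> 0). Vectorised.
#' @param ast Aspartate aminotransferase, IU/L (> 0). Vectorised.
#' @param coefficients List with `intercept`, `beta_bmi`, `beta_ast`;
#'   defaults to the published values.
#' @return Numeric score (dimensionless).
#' @export
bimast_score <- function(bmi, ast, coefficients = bimast_coefficients()) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ast)) || any(ast <= 0)) {
    stop("ast must be positive and finite", call. = FALSE)
  }
  coefficients$intercept + coefficients$beta_bmi * bmi +
    coefficients$beta_ast * ast
}

#' FIB-4 index
#'
#' Standard published formula: age * AST / (platelets * sqrt(ALT)), with
#' platelets in 10^9/L. Screening positivity here is FIB-4 > 1.3.
#'
#' @param age Years (> 0).
#' @param ast AST, IU/L (> 0).
#' @param alt ALT, IU/L (> 0).
#' @param platelets Platelet count, 10^9/L (> 0).
#' @return Numeric score. Vectorised.
#' @export
fib4 <- function(age, ast, alt, platelets) {
  for (x in list(age, ast, alt, platelets)) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("fib4 inputs must be positive and finite", call. = FALSE)
    }
  }
  age * ast / (platelets * sqrt(alt))
}

#' NAFLD fibrosis score
#'
#' Standard published formula:
#' -1.675 + 0.037*age + 0.094*BMI + 1.13*IFG/diabetes + 0.99*AST/ALT
#' - 0.013*platelets - 0.66*albumin, with albumin in g/dL. Screening
#' positivity here is NFS > -1.45. All subjects in this package's cohorts are
#' diabetic, so the diabetes term is 1 throughout the analyses.
#'
#' @param age Years (> 0).
#' @param bmi kg/m2 (> 0).
#' @param ast,alt IU/L (> 0).
#' @param platelets 10^9/L (> 0).
#' @param albumin g/dL (> 0). Note the cohort CSV stores albumin in g/L;
#'   divide by 10 at the interface.
#' @param diabetes Logical.
#' @return Numeric score. Vectorised.
#' @export
nfs <- function(age, bmi, ast, alt, platelets, albumin, diabetes) {
  for (x in list(age, bmi, ast, alt, platelets, albumin)) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("nfs inputs must be positive and finite", call. = FALSE)
    }
  }
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(diabetes) +
    0.99 * ast / alt - 0.013 * platelets - 0.66 * albumin
}

#' Classify a score against a threshold
#'
#' BIMAST, FIB-4 and NFS use a strict ">" rule; ELF and transient
#' elastography use an inclusive ">=" rule.
#'
#' @param value Score value(s).
#' @param threshold Decision threshold.
#' @param direction `"greater"` (strict) or `"greater_equal"`.
#' @return Logical: test-positive.
#' @export
classify <- function(value, threshold, direction = c("greater", "greater_equal")) {
  direction <- match.arg(direction)
  if (direction == "greater") value > threshold else value >= threshold
}

#' Screening strategy definitions
#'
#' The six screening strategies compared against standard of care (SOC).
#' Score-based strategies carry a score name, threshold and comparison
#' direction; US+LFTs and SOC are probabilistic classifiers with fixed
#' sensitivity/specificity (abnormal LFTs: 35% sensitivity, 65% specificity
#' for fibrosis; SOC mixes abnormal LFTs with no screening). Test costs are
#' GBP per person and sit with the health-economic placeholder parameter set.
#'
#' @param elf_threshold ELF positivity threshold (default 9.8; referral
#'   pathways elsewhere use 9.5).
#' @param soc_lfts_share Share of the SOC arm screened via abnormal LFTs;
#'   the remainder receives no screening (sensitivity 0, specificity 1).
#' @return Named list of `strategy_definition` objects with fields
#'   `name`, `kind` ("score" or "probabilistic"), `score`, `threshold`,
#'   `direction`, `sensitivity`, `specificity`, `test_cost`.
#' @export
strategy_definitions <- function(elf_threshold = 9.8, soc_lfts_share = 0.5) {
  score_strategy <- function(name, score, threshold, direction, test_cost) {
    structure(list(name = name, kind = "score", score = score,
                   threshold = threshold, direction = direction,
                   sensitivity = NA_real_, specificity = NA_real_,
                   test_cost = test_cost),
              class = "strategy_definition")
  }
  prob_strategy <- function(name, sens, spec, test_cost) {
    structure(list(name = name, kind = "probabilistic", score = NA_character_,
                   threshold = NA_real_, direction = NA_character_,
                   sensitivity = sens, specificity = spec,
                   test_cost = test_cost),
              class = "strategy_definition")
  }
  list(
    US_LFTS = prob_strategy("US_LFTS", sens = 0.35, spec = 0.65, test_cost = 58),
    FIB4 = score_strategy("FIB4", "fib4", 1.3, "greater", test_cost = 4),
    NFS = score_strategy("NFS", "nfs", -1.45, "greater", test_cost = 4),
    BIMAST = score_strategy("BIMAST", "bimast_prob", 0.063, "greater",
                            test_cost = 2),
    ELF = score_strategy("ELF", "elf", elf_threshold, "greater_equal",
                         test_cost = 45),
    TE = score_strategy("TE", "lsm", 8.1, "greater_equal", test_cost = 68),
    SOC = prob_strategy("SOC",
                        sens = soc_lfts_share * 0.35,
                        spec = soc_lfts_share * 0.65 + (1 - soc_lfts_share),
                        test_cost = 1)
  )
}

#' Compute a strategy's score for every subject in a cohort
#'
#' Note the screening cut-offs 0.063 (significant) and 0.102 (advanced
#' fibrosis) sit on the predicted-probability scale `"bimast_prob"` =
#' plogis(linear score): the published group-median linear scores (-0.517
#' fibrotic, -2.216 non-fibrotic) both lie far below 0.063, so a linear-scale
#' cut would contradict the published 94% sensitivity / 44% specificity,
#' whereas logit(0.063) = -2.70 reproduces that operating point.
#'
#' @param cohort Cohort data.frame.
#' @param score One of `"bimast"` (linear score), `"bimast_prob"`
#'   (predicted probability), `"fib4"`, `"nfs"`, `"elf"`, `"lsm"`.
#' @return Numeric vector of scores.
#' @export
cohort_scores <- function(cohort, score) {
  switch(score,
    bimast = bimast_score(cohort$bmi, cohort$ast),
    bimast_prob = stats::plogis(bimast_score(cohort$bmi, cohort$ast)),
    fib4 = fib4(cohort$age, cohort$ast, cohort$alt, cohort$platelets),
    nfs = nfs(cohort$age, cohort$bmi, cohort$ast, cohort$alt,
              cohort$platelets, cohort$albumin / 10, diabetes = TRUE),
    elf = cohort$elf,
    lsm = cohort$lsm,
    stop("unknown score: ", score, call. = FALSE)
  )
}

#' Build a confusion summary from truth and test labels
#'
#' @param truth Logical vector of disease status.
#' @param positive Logical vector of test positivity.
#' @return Object of class `confusion_summary`: counts `tp, fp, tn, fn` plus
#'   `sensitivity, specificity, ppv, npv, fn_rate` (NA where undefined).
#' @export
confusion_summary <- function(truth, positive) {
  stopifnot(length(truth) == length(positive))
  tp <- sum(truth & positive)
  fp <- sum(!truth & positive)
  tn <- sum(!truth & !positive)
  fn <- sum(truth & !positive)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn)
  out <- c(out, confusion_proportions(tp, fp, tn, fn))
  structure(out, class = "confusion_summary")
}

confusion_proportions <- function(tp, fp, tn, fn) {
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    fn_rate = safe_div(fn, tp + fn)
  )
}

#' Apply a screening strategy to a cohort
#'
#' Truth is LSM >= `truth_threshold` (8.1 kPa for significant, 12.1 kPa for
#' advanced fibrosis). Score strategies classify deterministically
#' (seed-independent); probabilistic strategies (US+LFTs, SOC) draw each
#' subject's result as a Bernoulli with the stated sensitivity (if diseased)
#' or 1 - specificity (if not), using `seed`.
#'
#' @param cohort Non-empty cohort data.frame.
#' @param strategy A `strategy_definition` (see [strategy_definitions()]).
#' @param truth_threshold 8.1 or 12.1 (kPa).
#' @param seed Integer seed, used only by probabilistic strategies.
#' @return A [confusion_summary()].
#' @export
apply_strategy <- function(cohort, strategy, truth_threshold = 8.1, seed = 1) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (!inherits(strategy, "strategy_definition")) {
    stop("unknown strategy: expected a strategy_definition", call. = FALSE)
  }
  if (!truth_threshold %in% c(8.1, 12.1)) {
    stop("truth_threshold must be 8.1 or 12.1 kPa", call. = FALSE)
  }
  truth <- cohort$lsm >= truth_threshold
  if (strategy$kind == "score") {
    positive <- classify(cohort_scores(cohort, strategy$score),
                         strategy$threshold, strategy$direction)
  } else {
    positive <- withr::with_seed(seed, {
      p <- ifelse(truth, strategy$sensitivity, 1 - strategy$specificity)
      stats::runif(nrow(cohort)) < p
    })
  }
  confusion_summary(truth, positive)
}

#' False-negative rate among diseased subjects
#'
#' fn / (tp + fn): the fraction of subjects with fibrosis missed at
#' screening.
#'
#' @param summary A [confusion_summary()].
#' @return Proportion in [0, 1].
#' @export
false_negative_rate <- function(summary) {
  if (summary$tp + summary$fn == 0) {
    stop("false-negative rate undefined: no diseased subjects", call. = FALSE)
  }
  summary$fn / (summary$tp + summary$fn)
}

#' Diagnostic metrics from a confusion summary
#'
#' @param summary A [confusion_summary()].
#' @return Named list `sensitivity, specificity, ppv, npv`; entries are NA
#'   (undefined-metric flag) when the corresponding denominator is zero.
#' @export
diagnostic_metrics <- function(summary) {
  p <- confusion_proportions(summary$tp, summary$fp, summary$tn, summary$fn)
  p[c("sensitivity", "specificity", "ppv", "npv")]
}
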