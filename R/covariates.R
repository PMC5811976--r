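#' Covariate specifications for transition-specific regression
#'
#' Describes how raw cohort columns are encoded into the model design matrix.
#' Continuous covariates may carry a reporting scale (e.g. age entered per 10
#' years so the hazard ratio is per decade); categorical covariates use
#' reference-level indicator coding.
#'
#' @param name covariate name (a cohort column).
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels declared levels (categorical only).
#' @param reference reference level; must be among `levels`.
#' @param scale positive divisor applied to continuous covariates before
#'   entering the model (reporting scale).
#' @return a `covariate_spec` object.
#' @export
covariate_spec <- function(name, kind = c("continuous", "categorical"),
                           levels = NULL, reference = NULL, scale = 1) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    stopifnot(!is.null(levels), length(levels) >= 2)
    if (is.null(reference)) reference <- levels[1]
    if (!reference %in% levels) stop("reference level not among declared levels")
  } else {
    if (!is.numeric(scale) || scale <= 0) stop("reporting scale must be > 0")
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference, scale = scale),
            class = "covariate_spec")
}

#' Default covariate set of the rectal-cancer chemotherapy model
#'
#' Age per 10 years; BMI per kg/m2; sex (reference male); UICC stage
#' (reference II); tumor grade (reference 1+2); chemotherapy arm (reference
#' 5-FU alone); operation type (reference abdominoperineal amputation).
#'
#' @return named list of `covariate_spec`s.
#' @export
fogt2_covariates <- function() {
  list(
    age = covariate_spec("age_years", "continuous", scale = 10),
    sex = covariate_spec("sex", "categorical",
                         levels = c("male", "female"), reference = "male"),
    grade = covariate_spec("grade", "categorical",
                           levels = c("1+2", "3+4"), reference = "1+2"),
    uicc = covariate_spec("uicc", "categorical",
                          levels = c("II", "IIIa", "IIIb", "IIIc"),
                          reference = "II"),
    bmi = covariate_spec("bmi", "continuous", scale = 1),
    arm = covariate_spec("arm", "categorical",
                         levels = c("5FU", "5FU_FA", "5FU_IFN"),
                         reference = "5FU"),
    surgery = covariate_spec("surgery", "categorical",
                             levels = c("abdominoperineal", "anterior_resection"),
                             reference = "abdominoperineal")
  )
}

# design-matrix column names implied by a list of covariate_specs
covariate_terms <- function(specs) {
  unlist(lapply(specs, function(sp) {
    if (sp$kind == "continuous") sp$name
    else paste0(sp$name, "_", make.names(setdiff(sp$levels, sp$reference)))
  }), use.names = FALSE)
}

#' Encode covariates into model terms
#'
#' Turns raw covariate columns into the numeric design columns used by the
#' transition-specific Cox models: continuous covariates divided by their
#' reporting scale, categorical covariates expanded to 0/1 indicators of the
#' non-reference levels.
#'
#' @param data data frame holding the raw covariate columns.
#' @param specs list of [covariate_spec()]s.
#' @return numeric data frame, one column per model term.
#' @export
encode_covariates <- function(data, specs) {
  if (!length(specs))
    return(as.data.frame(matrix(numeric(0), nrow = nrow(data), ncol = 0)))
  cols <- lapply(specs, function(sp) {
    x <- data[[sp$name]]
    if (is.null(x)) stop("missing covariate column: ", sp$name)
    if (sp$kind == "continuous") {
      out <- data.frame(as.numeric(x) / sp$scale)
      names(out) <- sp$name
      out
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x), sp$levels)
      if (length(bad)) stop("invalid level(s) for ", sp$name, ": ",
                            paste(bad, collapse = ", "))
      lv <- setdiff(sp$levels, sp$reference)
      out <- as.data.frame(lapply(lv, function(l) as.numeric(x == l)))
      names(out) <- paste0(sp$name, "_", make.names(lv))
      out
    }
  })
  do.call(cbind, unname(cols))
}

#' Reference patient profiles
#'
#' Named covariate profiles of hypothetical patients used for
#' covariate-specific prediction. The shipped presets are a high-risk patient
#' (UICC IIIc, grade 3+4, 5-FU alone) and a low-risk patient (UICC II, grade
#' 1+2, 5-FU + folinic acid); both male, 61 years old at start of
#' chemotherapy, BMI 25, anterior resection.
#'
#' @param which `"high_risk"`, `"low_risk"`, or a named list giving every raw
#'   covariate value.
#' @return a one-row data frame of raw covariate values (class
#'   `reference_patient`).
#' @export
reference_patient <- function(which = c("high_risk", "low_risk")) {
  if (is.list(which)) {
    prof <- as.data.frame(which, stringsAsFactors = FALSE)
  } else {
    which <- match.arg(which)
    prof <- data.frame(
      age_years = 61, bmi = 25, sex = "male",
      uicc = if (which == "high_risk") "IIIc" else "II",
      grade = if (which == "high_risk") "3+4" else "1+2",
      arm = if (which == "high_risk") "5FU" else "5FU_FA",
      surgery = "anterior_resection",
      stringsAsFactors = FALSE
    )
  }
  class(prof) <- c("reference_patient", "data.frame")
  prof
}
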