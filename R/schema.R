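# Lesion-level cohort schema: one row per treated radiosurgical target.

.schema_fields <- function() {
  list(
    list(name = "patient_id",  type = "id",      unit = NA,
         desc = "Opaque patient identifier; all lesions of a patient share it."),
    list(name = "lesion_id",   type = "id",      unit = NA,
         desc = "Opaque per-target identifier, unique within patient."),
    list(name = "age_years",   type = "numeric", unit = "years", min = 0,
         desc = "Age at treatment."),
    list(name = "sex",         type = "category", levels = c("M", "F"),
         desc = "Sex."),
    list(name = "kps",         type = "grid",    unit = "points",
         levels = seq(40, 100, by = 10),
         desc = "Karnofsky Performance Status before radiosurgery (40-100, steps of 10)."),
    list(name = "volume_cm3",  type = "numeric", unit = "cm3", min = 0, open_min = TRUE,
         desc = "Pre-treatment contrast-enhancing target volume."),
    list(name = "anatomic_loc", type = "category", levels = as.character(1:6),
         desc = paste("Anatomic localization: 1 frontal, 2 parietal, 3 occipital,",
                      "4 temporal, 5 cerebellar, 6 other/deep midline.")),
    list(name = "tumor_loc",   type = "category", levels = as.character(1:3),
         desc = "Tumor localization: 1 cortical/sub-cortical, 2 deep-seated/midline, 3 multifocal."),
    list(name = "dose_gy",     type = "numeric", unit = "Gy", min = 0, open_min = TRUE,
         desc = "Prescription dose at the covering isodose surface."),
    list(name = "isodose_pct", type = "numeric", unit = "%", min = 0, max = 100,
         open_min = TRUE,
         desc = "Prescription isodose line as percentage of maximum dose."),
    list(name = "max_gy",      type = "numeric", unit = "Gy", min = 0, open_min = TRUE,
         desc = "Maximum dose in the target; approximately dose_gy / (isodose_pct/100)."),
    list(name = "coverage",    type = "numeric", unit = "fraction", min = 0, max = 1,
         desc = "Fraction of the target covered by the prescription isodose."),
    list(name = "mgmt",        type = "category", levels = c("methyl", "unmethyl"),
         desc = "MGMT promoter methylation status."),
    list(name = "egfr",        type = "category", levels = c("ampl", "unampl", "mut", "unmut"),
         desc = "EGFR status as recorded (amplification and mutation vocabularies mixed in source coding)."),
    list(name = "pten",        type = "category", levels = c("mut", "umut"),
         desc = "PTEN status."),
    list(name = "tert",        type = "category", levels = c("mut", "unmut"),
         desc = "TERT promoter status."),
    list(name = "chr7p10q",    type = "category", levels = c("yes", "no"),
         desc = "Combined chromosome 7 gain / 10 loss signature."),
    list(name = "time_months", type = "numeric", unit = "months", min = 0, open_min = TRUE,
         mandatory = TRUE,
         desc = "Follow-up: months from radiosurgery to local failure or last imaging."),
    list(name = "event",       type = "event", mandatory = TRUE,
         desc = "1 = documented local failure, 0 = censored at last imaging.")
  )
}

# Verbose source-style column headers accepted on read, mapped to canonical
# names after case/punctuation normalization.
.schema_aliases <- c(
  "ageatdiagnosis"                     = "age_years",
  "age"                                = "age_years",
  "sexmf"                              = "sex",
  "kpsbeforesrsorrertforrecurrence"    = "kps",
  "presrsrtcontrastenhancingtumorvolumeincm3inclnecrosis" = "volume_cm3",
  "anatomiclocalization"               = "anatomic_loc",
  "tumorlocalization"                  = "tumor_loc",
  "srsdosegy"                          = "dose_gy",
  "prescriptiondosegy"                 = "dose_gy",
  "isodoseline"                        = "isodose_pct",
  "maxgy"                              = "max_gy",
  "mgmtmethylunmethylna"               = "mgmt",
  "egframplificationamplnonampl"       = "egfr",
  "ptenmutumut"                        = "pten",
  "tertmutunmut"                       = "tert",
  "chromosome710yesno"                 = "chr7p10q",
  "timemonths"                         = "time_months",
  "localfailure"                       = "event"
)

.canon_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Lesion-level cohort schema
#'
#' Returns the schema of the lesion-level cohort table: one row per treated
#' radiosurgical target, with clinical, tumor, molecular and plan covariates
#' plus right-censored time to local failure. A machine-readable JSON copy of
#' the same schema ships in `system.file("extdata", "cohort_schema.json",
#' package = "gksurv")`.
#'
#' @return A data frame with one row per field: `name`, `type`, `unit`,
#'   `levels` (slash-separated for categoricals), `mandatory`, `description`.
#' @export
cohort_schema <- function() {
  f <- .schema_fields()
  data.frame(
    name = vapply(f, `[[`, "", "name"),
    type = vapply(f, `[[`, "", "type"),
    unit = vapply(f, function(x) if (is.null(x$unit) || is.na(x$unit)) "" else x$unit, ""),
    levels = vapply(f, function(x)
      if (is.null(x$levels)) "" else paste(x$levels, collapse = "/"), ""),
    mandatory = vapply(f, function(x) isTRUE(x$mandatory), TRUE),
    description = vapply(f, `[[`, "", "desc"),
    stringsAsFactors = FALSE
  )
}

.schema_names <- function() vapply(.schema_fields(), `[[`, "", "name")

#' Construct and validate a lesion cohort
#'
#' Coerces a data frame holding the schema columns (see [cohort_schema()])
#' into a validated `lesion_cohort`. Categorical fields are stored as
#' character with `NA` for missing; out-of-range or off-level values raise an
#' error here (use [read_cohort()] for tolerant parsing of raw files).
#'
#' @param x A data frame with the schema columns.
#' @param provenance Free-text source tag stored as an attribute.
#' @return An object of class `lesion_cohort` (a data frame).
#' @export
as_lesion_cohort <- function(x, provenance = "in-memory") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.schema_names(), names(x))
  if (length(miss) > 0)
    stop("missing schema column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (f in .schema_fields()) {
    v <- x[[f$name]]
    x[[f$name]] <- switch(f$type,
      id = as.character(v),
      numeric = as.numeric(v),
      grid = as.numeric(v),
      category = as.character(v),
      event = as.integer(v))
  }
  rownames(x) <- NULL
  class(x) <- c("lesion_cohort", "data.frame")
  attr(x, "provenance") <- provenance
  validate_cohort(x)
  x
}

#' Validate lesion-cohort invariants
#'
#' Checks the structural invariants of a cohort: unique
#' (`patient_id`, `lesion_id`) pairs, strictly positive follow-up times,
#' `event` in \{0, 1\}, positive doses and volumes, and categorical values
#' restricted to their declared levels (or missing).
#'
#' @param cohort A `lesion_cohort`.
#' @param require_events If `TRUE`, additionally require at least one
#'   `event == 1` row (model-fitting entry points need this).
#' @return Invisibly, `cohort`; errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort, require_events = FALSE) {
  stopifnot(is.data.frame(cohort))
  key <- paste(cohort$patient_id, cohort$lesion_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient_id, lesion_id) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (nrow(cohort) > 0) {
    if (any(is.na(cohort$time_months)) || any(cohort$time_months <= 0))
      stop("time_months must be present and strictly positive for every row")
    if (any(is.na(cohort$event)) || !all(cohort$event %in% c(0L, 1L)))
      stop("event must be 0 or 1 for every row")
    if (any(is.na(cohort$dose_gy)) || any(cohort$dose_gy <= 0))
      stop("dose_gy must be present and strictly positive")
    for (f in .schema_fields()) {
      if (f$type == "category") {
        v <- cohort[[f$name]]
        bad <- !is.na(v) & !(v %in% f$levels)
        if (any(bad))
          stop(sprintf("field '%s' has values outside declared levels: %s",
                       f$name, paste(unique(v[bad]), collapse = ", ")))
      }
      if (f$type == "grid") {
        v <- cohort[[f$name]]
        bad <- !is.na(v) & !(v %in% f$levels)
        if (any(bad))
          stop(sprintf("field '%s' has off-grid values: %s",
                       f$name, paste(unique(v[bad]), collapse = ", ")))
      }
    }
  }
  if (require_events && sum(cohort$event == 1L) == 0)
    stop("cohort contains no local-failure events; model fitting requires at least one")
  invisible(cohort)
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("Lesion-level cohort: %d targets, %d patients, %d local failures (%.1f%%)\n",
              nrow(x), length(unique(x$patient_id)), sum(x$event == 1L),
              if (nrow(x) > 0) 100 * mean(x$event == 1L) else 0))
  cat(sprintf("Provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  if (nrow(x) > 0) {
    cat(sprintf("Follow-up: median %.1f months; dose: median %.1f Gy (range %.1f-%.1f)\n",
                median(x$time_months), median(x$dose_gy),
                min(x$dose_gy), max(x$dose_gy)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
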