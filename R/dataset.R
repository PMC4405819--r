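# Dataset model: a cohort of subjects plus their steady-state plasma
# concentration observations, exchanged as a NONMEM-style rectangular CSV
# (one row per observation, subject-level covariates repeated on each row).

genotype_levels <- list(
  cyp2b6_6   = c("GG", "GT", "TT"),
  cyp2b6_18  = c("TT", "TC", "CC"),
  cyp2a6_9   = c("GG", "GT", "TT"),
  cyp2a6_17  = c("GG", "GA", "AA"),
  abcb1_1236 = c("CC", "CT", "TT")
)

subject_columns <- c("id", "sex", "weight", "age", "cyp2b6_6", "cyp2b6_18",
                     "cyp2a6_9", "cyp2a6_17", "abcb1_1236", "regimen",
                     "cns", "dose", "tau")

#' Construct a PK dataset
#'
#' Bundles a subject table (one row per individual, demographic and
#' pharmacogenetic covariates, daily dose and dosing interval) with an
#' observation table (one row per plasma concentration sample) and
#' validates the pair. Concentrations are in ug/ml; `time` is hours after
#' the most recent dose at steady state, in `(0, tau]`.
#'
#' @param subjects data.frame with columns `id`, `sex` ("male"/"female"),
#'   `weight` (kg), `age` (years), genotype columns `cyp2b6_6`,
#'   `cyp2b6_18`, `cyp2a6_9`, `cyp2a6_17`, `abcb1_1236`, `regimen`
#'   ("ART_only"/"ART_plus_TB"), `cns` ("yes"/"no"), `dose` (mg/day),
#'   `tau` (h, 24 by default).
#' @param observations data.frame with columns `id`, `time` (h after
#'   dose), `conc` (ug/ml), `occ` (occasion, integer >= 1). May have zero
#'   rows for a covariates-only cohort.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects, observations = empty_observations()) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!"tau" %in% names(subjects)) subjects$tau <- 24
  if (!"occ" %in% names(observations) && nrow(observations) > 0)
    observations$occ <- 1L
  ds <- structure(list(subjects = subjects, observations = observations),
                  class = "pk_dataset")
  validate_pk_dataset(ds)
  ds
}

empty_observations <- function() {
  data.frame(id = character(), time = numeric(), conc = numeric(),
             occ = integer(), stringsAsFactors = FALSE)
}

validate_pk_dataset <- function(ds) {
  s <- ds$subjects
  o <- ds$observations
  missing_s <- setdiff(subject_columns, names(s))
  if (length(missing_s))
    stop("subjects table is missing column(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s$id))
    stop("duplicated subject id(s): ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "),
         call. = FALSE)
  if (!all(s$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(is.finite(s$weight)) || any(s$weight <= 0))
    stop("weight must be finite and positive", call. = FALSE)
  if (any(!is.finite(s$dose)) || any(s$dose <= 0))
    stop("dose must be positive", call. = FALSE)
  if (any(!is.finite(s$tau)) || any(s$tau <= 0))
    stop("tau must be positive", call. = FALSE)
  for (g in names(genotype_levels)) {
    bad <- !(s[[g]] %in% genotype_levels[[g]])
    if (any(bad))
      stop("invalid ", g, " genotype '", s[[g]][which(bad)[1]],
           "' for subject ", s$id[which(bad)[1]], call. = FALSE)
  }
  if (!all(s$regimen %in% c("ART_only", "ART_plus_TB")))
    stop("regimen must be 'ART_only' or 'ART_plus_TB'", call. = FALSE)
  if (!all(s$cns %in% c("yes", "no")))
    stop("cns must be 'yes' or 'no'", call. = FALSE)
  if (nrow(o) > 0) {
    missing_o <- setdiff(c("id", "time", "conc"), names(o))
    if (length(missing_o))
      stop("observations table is missing column(s): ",
           paste(missing_o, collapse = ", "), call. = FALSE)
    orphan <- !(o$id %in% s$id)
    if (any(orphan))
      stop("observation references unknown subject id '",
           o$id[which(orphan)[1]], "'", call. = FALSE)
    tau <- s$tau[match(o$id, s$id)]
    if (any(o$time <= 0 | o$time > tau))
      stop("observation times must lie in (0, tau]", call. = FALSE)
    if (any(!is.finite(o$conc)) || any(o$conc < 0))
      stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("<pk_dataset> ", nrow(x$subjects), " subjects, ",
      nrow(x$observations), " observations\n", sep = "")
  if (nrow(x$subjects)) {
    cat("  sex: ", sum(x$subjects$sex == "male"), " M / ",
        sum(x$subjects$sex == "female"), " F; median weight ",
        round(stats::median(x$subjects$weight), 1), " kg\n", sep = "")
    cat("  dose: ", paste(unique(x$subjects$dose), collapse = ", "),
        " mg q", paste(unique(x$subjects$tau), collapse = "/"),
        "h\n", sep = "")
  }
  invisible(x)
}

#' Column-name dialect for NONMEM-style CSV files
#'
#' Maps internal field names to file column names. Defaults follow the
#' rectangular layout conventional in population-PK datasets.
#'
#' @param ... overrides, e.g. `DV = "CONC"` renames the concentration
#'   column expected in the file.
#' @return Named character vector (internal field -> file column).
#' @export
nonmem_dialect <- function(...) {
  d <- c(id = "ID", time = "TIME", conc = "DV", dose = "DOSE", tau = "TAU",
         weight = "WT", sex = "SEX", age = "AGE",
         cyp2b6_6 = "CYP2B6_6", cyp2b6_18 = "CYP2B6_18",
         cyp2a6_9 = "CYP2A6_9", cyp2a6_17 = "CYP2A6_17",
         abcb1_1236 = "ABCB1", regimen = "GRP", cns = "CNS", occ = "OCC")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    d[names(ov)] <- ov
  }
  d
}

required_fields <- c("id", "time", "conc", "dose", "weight", "sex",
                     "cyp2b6_6", "cyp2b6_18", "cyp2a6_9", "cyp2a6_17",
                     "abcb1_1236")

#' Read a PK dataset from a NONMEM-style CSV file
#'
#' Expects one row per observation with subject-level covariates repeated.
#' Rows with a missing concentration (DV) are dropped with a message.
#' Sex is accepted as 0/1 (0 = male) or as "male"/"female" strings.
#' Concentration units are taken as ug/ml; no unit conversion is applied.
#'
#' @param path CSV file with a header row.
#' @param dialect column mapping from [nonmem_dialect()].
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, dialect = nonmem_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- dialect[required_fields]
  missing_col <- setdiff(unname(need), names(raw))
  if (length(missing_col))
    stop("required column(s) missing from ", path, ": ",
         paste(missing_col, collapse = ", "), call. = FALSE)

  getcol <- function(field, default = NULL) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]]
    else if (!is.null(default)) rep(default, nrow(raw))
    else stop("required column missing: ", col, call. = FALSE)
  }

  dv_raw <- getcol("conc")
  keep <- !(is.na(dv_raw) | dv_raw == "" | dv_raw == ".")
  if (any(!keep))
    message(sum(!keep), " row(s) dropped: missing DV (rows ",
            paste(utils::head(which(!keep), 10), collapse = ", "), ")")
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0) stop("no usable observation rows in ", path,
                           call. = FALSE)

  num <- function(field, default = NULL) {
    v <- suppressWarnings(as.numeric(getcol(field, default)))
    if (anyNA(v))
      stop("non-numeric value in column ", dialect[[field]], " (row ",
           which(is.na(v))[1], ")", call. = FALSE)
    v
  }
  sex_raw <- getcol("sex")
  sex <- ifelse(sex_raw %in% c("0", "male"), "male",
         ifelse(sex_raw %in% c("1", "female"), "female", NA))
  if (anyNA(sex))
    stop("unrecognised SEX code '", sex_raw[which(is.na(sex))[1]],
         "' (row ", which(is.na(sex))[1], ")", call. = FALSE)

  geno <- list()
  for (g in names(genotype_levels)) {
    v <- getcol(g)
    bad <- !(v %in% genotype_levels[[g]])
    if (any(bad))
      stop("invalid ", dialect[[g]], " genotype '", v[which(bad)[1]],
           "' (row ", which(bad)[1], ")", call. = FALSE)
    geno[[g]] <- v
  }

  id <- getcol("id")
  obs <- data.frame(id = id, time = num("time"), conc = num("conc"),
                    occ = as.integer(num("occ", "1")),
                    stringsAsFactors = FALSE)
  first <- !duplicated(id)
  subjects <- data.frame(
    id = id[first], sex = sex[first], weight = num("weight")[first],
    stringsAsFactors = FALSE)
  age_col <- dialect[["age"]]          # AGE is optional
  subjects$age <- if (age_col %in% names(raw))
    suppressWarnings(as.numeric(raw[[age_col]][first])) else NA_real_
  for (g in names(genotype_levels)) subjects[[g]] <- geno[[g]][first]
  subjects$regimen <- getcol("regimen", "ART_only")[first]
  subjects$cns <- getcol("cns", "no")[first]
  subjects$dose <- num("dose")[first]
  subjects$tau <- if (dialect[["tau"]] %in% names(raw)) num("tau")[first]
                  else 24
  pk_dataset(subjects, obs)
}

#' Write a PK dataset to a NONMEM-style CSV file
#'
#' Inverse of [read_pk_dataset()]: one row per observation with the
#' subject's covariates repeated. Sex is written as 0 (male) / 1 (female).
#'
#' @param ds a [pk_dataset()] with at least one observation.
#' @param path output file path.
#' @param dialect column mapping from [nonmem_dialect()].
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path, dialect = nonmem_dialect()) {
  validate_pk_dataset(ds)
  if (nrow(ds$observations) == 0)
    stop("dataset has no observations; nothing to write", call. = FALSE)
  s <- ds$subjects[match(ds$observations$id, ds$subjects$id), ]
  out <- data.frame(
    ds$observations$id, ds$observations$time, ds$observations$conc,
    s$dose, s$tau, s$weight, ifelse(s$sex == "female", 1L, 0L), s$age,
    s$cyp2b6_6, s$cyp2b6_18, s$cyp2a6_9, s$cyp2a6_17, s$abcb1_1236,
    s$regimen, s$cns, ds$observations$occ,
    stringsAsFactors = FALSE)
  names(out) <- unname(dialect[c("id", "time", "conc", "dose", "tau",
                                 "weight", "sex", "age", "cyp2b6_6",
                                 "cyp2b6_18", "cyp2a6_9", "cyp2a6_17",
                                 "abcb1_1236", "regimen", "cns", "occ")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
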