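#' Joint-area capacities
#'
#' Number of joints with the propensity to become damaged in each joint
#' area: 28 hand joints (14 per hand), 20 foot joints (10 per foot) and 16
#' large joints (left/right jaw, sterno-clavicular, shoulder, elbow,
#' wrist, hip, knee, ankle). Custom capacities are accepted so that small
#' enumerable toy designs can be built, e.g. for probability-coherence
#' checks.
#'
#' @param hands,feet,large positive integer capacities.
#' @return named integer vector with elements `hands`, `feet`, `large`.
#' @export
joint_capacities <- function(hands = 28L, feet = 20L, large = 16L) {
  caps <- c(hands = as.integer(hands), feet = as.integer(feet),
            large = as.integer(large))
  if (any(is.na(caps)) || any(caps < 1L))
    stop("capacities must be positive integers", call. = FALSE)
  caps
}

AREA_NAMES <- c("hands", "feet", "large")
DAMAGE_COLS <- paste0("damaged_", AREA_NAMES)
REQUIRED_COLS <- c("patient_id", "onset_time", "visit_time", DAMAGE_COLS)

#' Assemble and validate a visit-history dataset
#'
#' Takes a long-format table (one row per patient-visit) and returns a
#' validated `ms_data` object. Required columns: `patient_id`,
#' `onset_time` (arthritis onset, years), `visit_time` (years),
#' `damaged_hands`, `damaged_feet`, `damaged_large` (cumulative damaged
#' joint counts at the visit). Any further numeric columns (e.g.
#' `active_hands`) are carried along and may be used as visit-level
#' covariates.
#'
#' Validation enforces: counts are non-negative integers within the area
#' capacities; cumulative counts are non-decreasing over a patient's
#' visits; onset is no later than the first visit; visit times within a
#' patient are distinct (or merged, keeping the maximum counts, when
#' `merge_duplicates = TRUE` -- duplicate-date visits would otherwise
#' imply zero-length intervals for which no increment distribution is
#' defined). Rows are sorted by patient and visit time; errors name the
#' offending input rows.
#'
#' @param visits data frame of visits.
#' @param capacities named capacities from [joint_capacities()].
#' @param merge_duplicates merge same-day visits instead of erroring?
#' @return an object of class `ms_data`: list with `visits` (validated,
#'   sorted data frame), `capacities`, `patient_ids`, `n_patients`, and a
#'   `merge_log` describing any merged rows.
#' @export
visits_data <- function(visits, capacities = joint_capacities(),
                        merge_duplicates = FALSE) {
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(visits))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(visits) == 0L) stop("empty visits table", call. = FALSE)
  visits$.row <- seq_len(nrow(visits))

  for (k in AREA_NAMES) {
    col <- paste0("damaged_", k)
    v <- visits[[col]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("column '%s': non-integer or negative count at row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    over <- which(v > capacities[[k]])
    if (length(over))
      stop(sprintf(
        "column '%s': count exceeds the %s capacity (%d) at row(s) %s",
        col, k, capacities[[k]],
        paste(utils::head(over, 5L), collapse = ", ")), call. = FALSE)
  }

  ord <- order(visits$patient_id, visits$visit_time)
  visits <- visits[ord, , drop = FALSE]

  merge_log <- character(0)
  dup <- duplicated(visits[c("patient_id", "visit_time")])
  if (any(dup)) {
    if (!merge_duplicates)
      stop(sprintf(
        "duplicate visit date(s) for patient(s) %s (input row(s) %s); use merge_duplicates = TRUE to keep per-date maximum counts",
        paste(unique(visits$patient_id[dup]), collapse = ", "),
        paste(utils::head(visits$.row[dup], 5L), collapse = ", ")),
        call. = FALSE)
    key <- interaction(visits$patient_id, visits$visit_time, drop = TRUE)
    num_cols <- setdiff(names(visits)[vapply(visits, is.numeric, TRUE)],
                        c("visit_time", "onset_time", ".row"))
    merged <- visits[!duplicated(key), , drop = FALSE]
    mkey <- key[!duplicated(key)]
    for (col in num_cols) {
      mx <- tapply(visits[[col]], key, max)
      merged[[col]] <- as.vector(mx[as.character(mkey)])
    }
    merge_log <- sprintf("merged %d duplicate-date row(s), keeping maxima",
                         sum(dup))
    visits <- merged
  }

  sp <- split(visits, visits$patient_id)
  for (pid in names(sp)) {
    h <- sp[[pid]]
    if (length(unique(h$onset_time)) != 1L)
      stop(sprintf("patient %s: onset_time must be constant", pid),
           call. = FALSE)
    if (h$onset_time[1L] > h$visit_time[1L] + 1e-12)
      stop(sprintf("patient %s: onset_time is after the first visit", pid),
           call. = FALSE)
    for (k in AREA_NAMES) {
      v <- h[[paste0("damaged_", k)]]
      if (any(diff(v) < 0))
        stop(sprintf(
          "patient %s: decreasing cumulative %s count at input row(s) %s",
          pid, k,
          paste(h$.row[which(diff(v) < 0) + 1L], collapse = ", ")),
          call. = FALSE)
    }
  }

  visits$.row <- NULL
  rownames(visits) <- NULL
  structure(list(visits = visits, capacities = capacities,
                 patient_ids = names(sp), n_patients = length(sp),
                 merge_log = merge_log),
            class = "ms_data")
}

#' @export
print.ms_data <- function(x, ...) {
  nv <- nrow(x$visits)
  cat(sprintf("Visit histories: %d patients, %d visits (%.1f per patient)\n",
              x$n_patients, nv, nv / x$n_patients))
  ever <- vapply(AREA_NAMES, function(k) {
    fin <- tapply(x$visits[[paste0("damaged_", k)]], x$visits$patient_id, max)
    mean(fin > 0)
  }, numeric(1))
  cat(sprintf("Capacities: hands %d, feet %d, large %d\n",
              x$capacities[["hands"]], x$capacities[["feet"]],
              x$capacities[["large"]]))
  cat(sprintf("Ever-damaged fraction: hands %.2f, feet %.2f, large %.2f\n",
              ever[1], ever[2], ever[3]))
  invisible(x)
}

#' @export
as.data.frame.ms_data <- function(x, ...) x$visits

#' Read a visit-history CSV
#'
#' Reads the long-format visits CSV (see [visits_data()] for the schema)
#' and validates it.
#'
#' @param path CSV file path.
#' @inheritParams visits_data
#' @return an `ms_data` object.
#' @export
read_visits <- function(path, capacities = joint_capacities(),
                        merge_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  visits_data(utils::read.csv(path, stringsAsFactors = FALSE),
              capacities = capacities, merge_duplicates = merge_duplicates)
}

#' Write a visit-history CSV
#'
#' @param data an `ms_data` object (or plain visits data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(data, path) {
  df <- if (inherits(data, "ms_data")) data$visits else as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
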