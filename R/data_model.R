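#' @importFrom rlang .data abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

COMPARTMENTS <- c("CD", "CC", "PC")

#' Covered-codend selectivity dataset
#'
#' Bundles haul-level length-frequency counts from a covered-codend (or
#' dual-cover) selectivity experiment. Each row of `data` holds, for one haul
#' and one 1-cm length class, the number of fish length-measured in the codend
#' (`n_CD`), the codend cover (`n_CC`) and, for gears with a square mesh panel
#' (SMP), the panel cover (`n_PC`), together with the per-haul subsampling
#' factors `q_CD`, `q_CC`, `q_PC` (ratio of length-measured to total fish in
#' the compartment, in (0, 1]). Length classes are labelled by their lower
#' bound in cm (fish measured to the nearest centimetre below).
#'
#' Rows with identical (haul, length class) are summed, tolerating
#' concatenated field sheets; subsampling factors must agree within a haul.
#'
#' @param data Data frame with columns `haul_id`, `length_cm`, `n_CD`, `n_CC`,
#'   `q_CD`, `q_CC` and optionally `n_PC`, `q_PC` (both or neither).
#' @param gear Optional gear label (e.g. `"SMP_BS+CD_D"`).
#' @param species Optional species label.
#' @return An object of class `selectivity_dataset`: a list with elements
#'   `data` (canonicalized tibble), `gear`, `species`, `has_pc`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   haul_id = 1, length_cm = 20:24,
#'   n_CD = c(2, 5, 9, 12, 15), n_CC = c(8, 6, 4, 2, 1),
#'   q_CD = 1, q_CC = 1
#' )
#' selectivity_dataset(d, gear = "CD_D", species = "hake")
selectivity_dataset <- function(data, gear = NA_character_, species = NA_character_) {
  data <- as_tibble(data)
  required <- c("haul_id", "length_cm", "n_CD", "n_CC", "q_CD", "q_CC")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "trawlselect_schema_error")
  }
  has_pc <- "n_PC" %in% names(data)
  if (has_pc && !"q_PC" %in% names(data)) {
    abort("column n_PC present but q_PC missing", class = "trawlselect_schema_error")
  }
  if (!has_pc && "q_PC" %in% names(data)) data$q_PC <- NULL
  if (nrow(data) == 0) {
    abort("dataset has no rows", class = "trawlselect_validation_error")
  }

  count_cols <- paste0("n_", if (has_pc) COMPARTMENTS else c("CD", "CC"))
  q_cols <- sub("^n_", "q_", count_cols)
  for (cc in c(count_cols, q_cols, "length_cm")) {
    if (!is.numeric(data[[cc]])) {
      abort(paste0("column ", cc, " must be numeric"), class = "trawlselect_validation_error")
    }
  }
  bad <- which(Reduce(`|`, lapply(count_cols, function(cc) data[[cc]] < 0 | !is.finite(data[[cc]]))))
  if (length(bad) > 0) {
    abort(paste0("negative or non-finite count at row(s): ", paste(utils::head(bad, 5), collapse = ", ")),
          class = "trawlselect_validation_error")
  }
  bad_q <- which(Reduce(`|`, lapply(q_cols, function(qc) data[[qc]] <= 0 | data[[qc]] > 1 | !is.finite(data[[qc]]))))
  if (length(bad_q) > 0) {
    abort(paste0("subsampling factor outside (0, 1] at row(s): ", paste(utils::head(bad_q, 5), collapse = ", ")),
          class = "trawlselect_validation_error")
  }
  if (any(data$length_cm < 0)) {
    abort("length_cm must be >= 0", class = "trawlselect_validation_error")
  }

  # q must be constant within haul; counts for duplicate (haul, length) rows sum
  q_chk <- data |>
    group_by(.data$haul_id) |>
    summarise(across(all_of(q_cols), ~ n_distinct(.x)), .groups = "drop")
  if (any(as.matrix(q_chk[q_cols]) > 1)) {
    abort("subsampling factors differ within a haul", class = "trawlselect_validation_error")
  }
  data <- data |>
    group_by(.data$haul_id, .data$length_cm) |>
    summarise(across(all_of(count_cols), sum), across(all_of(q_cols), first),
              .groups = "drop") |>
    arrange(.data$haul_id, .data$length_cm)

  structure(
    list(data = data, gear = gear, species = species, has_pc = has_pc),
    class = "selectivity_dataset"
  )
}

#' @export
print.selectivity_dataset <- function(x, ...) {
  cat("<selectivity_dataset>",
      if (!is.na(x$gear)) paste0(" gear: ", x$gear),
      if (!is.na(x$species)) paste0(" species: ", x$species), "\n", sep = "")
  cat("  ", n_hauls(x), " haul(s), ",
      length(unique(x$data$length_cm)), " length classes (",
      min(x$data$length_cm), "-", max(x$data$length_cm), " cm), ",
      if (x$has_pc) "dual cover (CD/CC/PC)" else "codend cover only (CD/CC)",
      "\n", sep = "")
  invisible(x)
}

#' Number of hauls in a dataset
#' @param ds A [selectivity_dataset()].
#' @return Integer haul count.
#' @export
n_hauls <- function(ds) {
  stopifnot(inherits(ds, "selectivity_dataset"))
  length(unique(ds$data$haul_id))
}

#' Read a covered-codend dataset from CSV
#'
#' Expects the canonical schema `haul_id, length_cm, n_CD, n_CC, q_CD, q_CC`
#' with optional `n_PC, q_PC`; `schema` renames nonstandard column headers.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(n_CD = "codend_count")`.
#' @inheritParams selectivity_dataset
#' @return A [selectivity_dataset()].
#' @export
read_selectivity <- function(path, schema = NULL, gear = NA_character_,
                             species = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        abort(paste0("schema column not in file: ", src), class = "trawlselect_schema_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  selectivity_dataset(raw, gear = gear, species = species)
}

#' Write a covered-codend dataset to CSV
#'
#' Inverse of [read_selectivity()]: the canonical schema is written so that a
#' read/write round trip reproduces the dataset (PC columns only when present).
#'
#' @param ds A [selectivity_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selectivity <- function(ds, path) {
  stopifnot(inherits(ds, "selectivity_dataset"))
  readr::write_csv(ds$data, path, progress = FALSE)
  invisible(path)
}

#' Drop length classes that could escape through the cover meshes
#'
#' Cover meshes retain escapees imperfectly at the smallest sizes, so length
#' classes at or below a threshold are excluded per cover: panel-cover (PC)
#' counts at classes `<= min_pc_cm` and codend-cover (CC) counts at classes
#' `<= min_cc_cm` are removed. Codend (CD) counts are never touched. The
#' operation is idempotent and never increases a count.
#'
#' @param ds A [selectivity_dataset()].
#' @param min_pc_cm,min_cc_cm Length thresholds in cm (defaults 20 and 15, the
#'   conventional cutoffs for the gears this package models).
#' @return A new filtered [selectivity_dataset()]; the input is unmodified.
#' @export
apply_length_filters <- function(ds, min_pc_cm = 20, min_cc_cm = 15) {
  stopifnot(inherits(ds, "selectivity_dataset"), min_pc_cm >= 0, min_cc_cm >= 0)
  d <- ds$data
  d$n_CC[d$length_cm <= min_cc_cm] <- 0
  if (ds$has_pc) d$n_PC[d$length_cm <= min_pc_cm] <- 0
  out <- ds
  out$data <- d
  out
}

#' Raise measured counts by their subsampling factors
#'
#' Divides each measured count by the compartment's subsampling factor `q`,
#' converting length-measured fish to estimated total fish per compartment.
#'
#' @param ds A [selectivity_dataset()] (may hold one or many hauls).
#' @return A tibble with columns `haul_id`, `length_cm`, `compartment`,
#'   `n` (measured) and `n_raised = n / q`.
#' @export
raise_counts <- function(ds) {
  stopifnot(inherits(ds, "selectivity_dataset"))
  comps <- if (ds$has_pc) COMPARTMENTS else c("CD", "CC")
  purrr::map_dfr(comps, function(cp) {
    tibble(
      haul_id = ds$data$haul_id,
      length_cm = ds$data$length_cm,
      compartment = cp,
      n = ds$data[[paste0("n_", cp)]],
      q = ds$data[[paste0("q_", cp)]]
    )
  }) |>
    mutate(n_raised = .data$n / .data$q) |>
    arrange(.data$haul_id, .data$length_cm, .data$compartment)
}

#' Pool raised counts over hauls
#'
#' Sums the raised counts of [raise_counts()] across hauls, giving the pooled
#' per-compartment length frequency that the pooled binomial likelihood uses.
#'
#' @param ds A [selectivity_dataset()].
#' @return A tibble with columns `compartment`, `length_cm`, `n_raised`.
#' @export
pool_over_hauls <- function(ds) {
  raise_counts(ds) |>
    group_by(.data$compartment, .data$length_cm) |>
    summarise(n_raised = sum(.data$n_raised), .groups = "drop") |>
    arrange(.data$compartment, .data$length_cm)
}

#' Evaluation point of a 1-cm length class
#'
#' Length classes are labelled by their lower bound; retention curves applied
#' to binned data are evaluated at the class midpoint (`label + 0.5`) by
#' default, which minimizes binning bias, or at the lower bound.
#'
#' @param length_cm Numeric vector of class labels (lower bounds, cm).
#' @param at `"midpoint"` (default) or `"lower"`.
#' @return Numeric vector of evaluation lengths.
#' @export
class_mark <- function(length_cm, at = c("midpoint", "lower")) {
  at <- match.arg(at)
  if (at == "midpoint") length_cm + 0.5 else length_cm
}
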