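#' Read and validate a plant-microherbivore interaction edge list
#'
#' Reads the edge-list CSV (or takes an equivalent data frame), maps plant
#' names through an optional synonym table, drops records identified only to
#' plant genus, and collapses exact duplicates so each (plant, herbivore)
#' pair is one association.
#'
#' @param x Path to a CSV with columns `plant_name` and `herbivore_name`
#'   (optional `plant_rank` with values `"species"`/`"genus-only"`), or a
#'   data frame with those columns. When no rank column is present, a
#'   one-token plant name is treated as genus-only.
#' @param synonym_map Optional data frame with columns `name` and
#'   `accepted_name`; plant names are mapped before de-duplication.
#' @return Tibble with columns `plant_name`, `herbivore_name`; attributes
#'   `n_genus_only` and `n_duplicates` record dropped and collapsed rows.
#' @export
read_interactions <- function(x, synonym_map = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    df <- readr::read_csv(x, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  } else {
    df <- tibble::as_tibble(x)
  }
  required <- c("plant_name", "herbivore_name")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("interaction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("interaction table is empty", call. = FALSE)
  df$plant_name <- trimws(df$plant_name)
  df$herbivore_name <- trimws(df$herbivore_name)
  if (any(!nzchar(df$plant_name)) || any(!nzchar(df$herbivore_name))) {
    stop("empty taxon names in interaction table", call. = FALSE)
  }

  if (!is.null(synonym_map)) {
    stopifnot(all(c("name", "accepted_name") %in% names(synonym_map)))
    idx <- match(df$plant_name, synonym_map$name)
    hit <- !is.na(idx)
    df$plant_name[hit] <- synonym_map$accepted_name[idx[hit]]
  }

  if ("plant_rank" %in% names(df)) {
    genus_only <- df$plant_rank == "genus-only"
  } else {
    genus_only <- !grepl("\\s", df$plant_name)
  }
  n_genus_only <- sum(genus_only)
  df <- df[!genus_only, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no species-level interaction records remain", call. = FALSE)
  }

  out <- dplyr::distinct(df, .data$plant_name, .data$herbivore_name)
  n_dup <- nrow(df) - nrow(out)
  message(sprintf(
    "read_interactions: %d associations (%d genus-only dropped, %d duplicates collapsed)",
    nrow(out), n_genus_only, n_dup))
  attr(out, "n_genus_only") <- n_genus_only
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Read a plant attribute table
#'
#' @param x Path to a CSV (or a data frame) with at least `accepted_name`,
#'   `genus`, `family`, `origin` (`"native"`/`"non-native"`) and `woodiness`
#'   (`"woody"`/`"non-woody"`/`"unknown"`); other columns pass through.
#' @return Tibble of plant records.
#' @export
read_plants <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    df <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- tibble::as_tibble(x)
  }
  required <- c("accepted_name", "genus", "family", "origin", "woodiness")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("plant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$origin), c("native", "non-native"))
  if (length(bad) > 0) {
    stop("unrecognised origin value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$accepted_name)) {
    stop("duplicated accepted_name in plant table", call. = FALSE)
  }
  df
}

#' Microherbivory richness per plant
#'
#' Richness is the number of distinct microherbivore species documented on a
#' plant. Summed over plants it equals the number of distinct
#' (plant, herbivore) associations.
#'
#' @param interactions Edge list as returned by [read_interactions()].
#' @return Tibble with columns `plant_name`, `richness`.
#' @export
richness_per_plant <- function(interactions) {
  stopifnot(all(c("plant_name", "herbivore_name") %in% names(interactions)))
  if (nrow(interactions) == 0L) {
    stop("interaction table is empty", call. = FALSE)
  }
  interactions |>
    dplyr::distinct(.data$plant_name, .data$herbivore_name) |>
    dplyr::count(.data$plant_name, name = "richness")
}
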