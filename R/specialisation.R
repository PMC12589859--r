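#' Host breadth of each microherbivore
#'
#' Host breadth is the number of distinct plant species (native and
#' non-native alike) a microherbivore uses across the full dataset. It is
#' computed before any integration filtering.
#'
#' @param interactions Edge list with `plant_name`, `herbivore_name`.
#' @return Tibble with columns `herbivore_name`, `n_host_species`.
#' @export
host_breadth <- function(interactions) {
  stopifnot(all(c("plant_name", "herbivore_name") %in% names(interactions)))
  if (nrow(interactions) == 0L) stop("interaction table is empty", call. = FALSE)
  interactions |>
    dplyr::distinct(.data$herbivore_name, .data$plant_name) |>
    dplyr::count(.data$herbivore_name, name = "n_host_species")
}

#' Host-specialisation (phagy) class from host counts
#'
#' Assigns each microherbivore one of four classes from its counts of
#' distinct host species, genera and families: monophagous (one host
#' species); oligophagous (more than one host species across at most four
#' genera within one family); mesophagous (more than one host species across
#' more than one genus within at most three families); polyphagous
#' (otherwise). Rules are applied narrow to broad, so a profile satisfying
#' both the oligophagous and mesophagous conditions is oligophagous.
#'
#' @param n_host_species,n_host_genera,n_host_families Integer vectors of
#'   equal length. Must satisfy `1 <= families <= genera <= species`, with
#'   single-species profiles having one genus and one family.
#' @return Character vector of class labels.
#' @export
classify_phagy <- function(n_host_species, n_host_genera, n_host_families) {
  s <- n_host_species; g <- n_host_genera; f <- n_host_families
  n <- length(s)
  stopifnot(length(g) == n, length(f) == n)
  bad <- s < 1 | g < 1 | f < 1 | f > g | g > s | (s == 1 & (g != 1 | f != 1))
  if (any(bad)) {
    stop("inconsistent host counts at position(s): ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  out <- rep("polyphagous", n)
  out[s > 1 & g > 1 & f <= 3] <- "mesophagous"
  out[s > 1 & g <= 4 & f == 1] <- "oligophagous"
  out[s == 1] <- "monophagous"
  out
}

#' Full specialisation profile for every microherbivore
#'
#' Joins the edge list to plant taxonomy, counts distinct host species,
#' genera and families per microherbivore, and classifies phagy.
#'
#' @param interactions Edge list with `plant_name`, `herbivore_name`.
#' @param plants Plant table with `accepted_name`, `genus`, `family`.
#' @return Tibble `herbivore_name`, `n_host_species`, `n_host_genera`,
#'   `n_host_families`, `phagy`.
#' @export
herbivore_profiles <- function(interactions, plants) {
  stopifnot(all(c("accepted_name", "genus", "family") %in% names(plants)))
  unknown <- setdiff(interactions$plant_name, plants$accepted_name)
  if (length(unknown) > 0) {
    stop("plants in the edge list missing from the plant table: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  joined <- interactions |>
    dplyr::distinct(.data$herbivore_name, .data$plant_name) |>
    dplyr::left_join(
      dplyr::select(plants, plant_name = "accepted_name", "genus", "family"),
      by = "plant_name")
  prof <- joined |>
    dplyr::group_by(.data$herbivore_name) |>
    dplyr::summarise(
      n_host_species = dplyr::n_distinct(.data$plant_name),
      n_host_genera = dplyr::n_distinct(.data$genus),
      n_host_families = dplyr::n_distinct(.data$family),
      .groups = "drop")
  prof$phagy <- classify_phagy(prof$n_host_species, prof$n_host_genera,
                               prof$n_host_families)
  prof
}

#' Mean host breadth of the microherbivores on each plant
#'
#' For each plant, the arithmetic mean of the host breadths of its
#' interaction partners; larger values indicate that the plant's
#' microherbivores are, on average, more generalist.
#'
#' @param interactions Edge list with `plant_name`, `herbivore_name`.
#' @param breadths Tibble from [host_breadth()]. Every herbivore in the edge
#'   list must have a breadth.
#' @return Tibble `plant_name`, `mean_breadth`, `n_partners`.
#' @export
per_plant_mean_breadth <- function(interactions, breadths) {
  stopifnot(all(c("herbivore_name", "n_host_species") %in% names(breadths)))
  missing <- setdiff(interactions$herbivore_name, breadths$herbivore_name)
  if (length(missing) > 0) {
    stop("herbivores without a host breadth: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  interactions |>
    dplyr::distinct(.data$plant_name, .data$herbivore_name) |>
    dplyr::left_join(breadths, by = "herbivore_name") |>
    dplyr::group_by(.data$plant_name) |>
    dplyr::summarise(mean_breadth = mean(.data$n_host_species),
                     n_partners = dplyr::n(), .groups = "drop")
}

#' Restrict non-natives to trophically well-integrated species
#'
#' Keeps non-native plants whose European area of occupancy exceeds the
#' growth-form-specific integration threshold (strictly greater than
#' 270,000 km2 for woody and 1.1 million km2 for non-woody species, the
#' range sizes at which predicted richness reaches the native average).
#' Native plants pass untouched. Non-natives with unknown woodiness or
#' missing AOO cannot be assessed and are dropped.
#'
#' @param plants Plant table with `origin`, `woodiness`, `aoo_km2`.
#' @param woody_km2,nonwoody_km2 Thresholds in km2.
#' @return Filtered plant table; attribute `n_dropped` counts removed
#'   non-natives.
#' @export
integration_filter <- function(plants, woody_km2 = 270000,
                               nonwoody_km2 = 1.1e6) {
  stopifnot(all(c("origin", "woodiness", "aoo_km2") %in% names(plants)))
  native <- plants$origin == "native"
  thr <- ifelse(plants$woodiness == "woody", woody_km2,
                ifelse(plants$woodiness == "non-woody", nonwoody_km2, Inf))
  keep <- native | (!is.na(plants$aoo_km2) & plants$aoo_km2 > thr)
  out <- plants[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Specialisation composition of each plant's partners, summarised by group
#'
#' Computes, per plant, the proportion of its microherbivore partners in
#' each phagy class, then averages across plants within plant origin x
#' woodiness groups (`by = "group"`) or within residence-time bins among
#' non-natives (`by = "residence_bin"`). Averages may be weighted by each
#' plant's total recorded interactions.
#'
#' @param interactions Edge list with `plant_name`, `herbivore_name`.
#' @param profiles Tibble from [herbivore_profiles()] (needs `phagy`).
#' @param plants Plant table with `accepted_name`, `origin`, `woodiness`
#'   and, for residence bins, `intro_year`.
#' @param weights `"none"` for unweighted means, `"interactions"` to weight
#'   each plant by its number of recorded partners.
#' @param by Grouping: `"group"` or `"residence_bin"`.
#' @param bin_width Residence-bin width in years (default 50).
#' @param reference_year Year from which residence time is counted.
#' @return Tibble in long form: grouping columns, `phagy`, `proportion`,
#'   `n_plants`. Proportions sum to 1 within each group.
#' @export
composition_summary <- function(interactions, profiles, plants,
                                weights = c("none", "interactions"),
                                by = c("group", "residence_bin"),
                                bin_width = 50, reference_year = 2025) {
  weights <- match.arg(weights)
  by <- match.arg(by)
  phagy_levels <- c("monophagous", "oligophagous", "mesophagous",
                    "polyphagous")
  per_plant <- interactions |>
    dplyr::distinct(.data$plant_name, .data$herbivore_name) |>
    dplyr::left_join(
      dplyr::select(profiles, "herbivore_name", "phagy"),
      by = "herbivore_name")
  if (anyNA(per_plant$phagy)) {
    stop("edge list contains herbivores missing from the profiles",
         call. = FALSE)
  }
  comp <- per_plant |>
    dplyr::group_by(.data$plant_name) |>
    dplyr::summarise(
      n_partners = dplyr::n(),
      proportion = list(as.vector(
        table(factor(.data$phagy, levels = phagy_levels)) / dplyr::n())),
      .groups = "drop") |>
    tidyr::unnest_wider("proportion", names_sep = "_") |>
    setNames(c("plant_name", "n_partners", phagy_levels))

  comp <- dplyr::left_join(
    comp,
    dplyr::select(plants, plant_name = "accepted_name",
                  dplyr::any_of(c("origin", "woodiness", "intro_year"))),
    by = "plant_name")
  comp$.w <- if (weights == "interactions") comp$n_partners else 1

  if (by == "group") {
    grouped <- dplyr::group_by(comp, .data$origin, .data$woodiness)
  } else {
    if (!"intro_year" %in% names(comp)) {
      stop("residence bins need an intro_year column in the plant table",
           call. = FALSE)
    }
    comp <- comp[comp$origin == "non-native" & !is.na(comp$intro_year), ]
    res <- reference_year - comp$intro_year
    comp$residence_bin <- floor(res / bin_width) * bin_width
    grouped <- dplyr::group_by(comp, .data$residence_bin)
  }
  grouped |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(phagy_levels),
                    ~ sum(.x * .data$.w) / sum(.data$.w)),
      n_plants = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(phagy_levels), names_to = "phagy",
                        values_to = "proportion")
}
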