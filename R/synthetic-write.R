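#' Write a complete synthetic raw dataset to disk
#'
#' Generates a flora and its interactions, then writes the raw CSV inputs
#' the pipeline consumes: `interactions.csv`, `plants.csv`,
#' `occurrences.csv`, `region_centroids.csv`, `synonyms.csv` and
#' `first_records.csv`, plus `truth.json` with the generating parameters
#' and per-plant latent values for parameter-recovery tests.
#'
#' The interaction file deliberately contains the blemishes real
#' compilations have: a configurable share of plant names replaced by a
#' synonym (resolved by `synonyms.csv`), a handful of genus-level records,
#' and duplicated rows. The first-records file holds one or more regional
#' records per species, including spurious pre-1492 records for a small
#' fraction of species.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the generated `plants`,
#'   `interactions` and `truth`.
#' @export
write_synthetic_dataset <- function(config, dir) {
  stopifnot(inherits(config, "troph_config"))
  cfg <- config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plants <- generate_flora(cfg)
  gen <- generate_interactions(plants, cfg)
  set.seed(sub_seed(cfg$seed, 2L))

  inter <- gen$interactions
  # synonym aliasing: a share of plants appears under an alias name
  n_syn <- round(cfg$synonym_fraction * nrow(plants))
  synonyms <- tibble::tibble(name = character(0), accepted_name = character(0))
  if (n_syn > 0) {
    aliased <- sample(plants$accepted_name, n_syn)
    alias <- paste0(sub(" .*$", "", aliased), " syn",
                    sprintf("%03d", seq_len(n_syn)))
    synonyms <- tibble::tibble(name = alias, accepted_name = aliased)
    idx <- match(inter$plant_name, synonyms$accepted_name)
    hit <- !is.na(idx)
    inter$plant_name[hit] <- synonyms$name[idx[hit]]
  }
  if (cfg$genus_only_records > 0) {
    inter <- dplyr::bind_rows(inter, tibble::tibble(
      plant_name = sample(plants$genus, cfg$genus_only_records,
                          replace = TRUE),
      herbivore_name = sample(unique(inter$herbivore_name),
                              cfg$genus_only_records, replace = TRUE)))
  }
  if (cfg$duplicate_records > 0 && nrow(inter) > 0) {
    dup <- inter[sample.int(nrow(inter),
                            min(cfg$duplicate_records, nrow(inter))), ]
    inter <- dplyr::bind_rows(inter, dup)
  }
  inter <- inter[sample.int(nrow(inter)), ]

  non <- plants[plants$origin == "non-native", ]
  occurrences <- NULL
  if (nrow(non) > 0) {
    occurrences <- tibble::tibble(
      species = rep.int(non$accepted_name,
                        vapply(non$cells, nrow, integer(1))),
      do.call(rbind, non$cells) |> tibble::as_tibble())
  } else {
    occurrences <- tibble::tibble(species = character(0), i = integer(0),
                                  j = integer(0))
  }

  first_records <- synth_first_records(non, cfg)

  paths <- list(
    interactions = file.path(dir, "interactions.csv"),
    plants = file.path(dir, "plants.csv"),
    occurrences = file.path(dir, "occurrences.csv"),
    region_centroids = file.path(dir, "region_centroids.csv"),
    synonyms = file.path(dir, "synonyms.csv"),
    first_records = file.path(dir, "first_records.csv"),
    truth = file.path(dir, "truth.json"))

  readr::write_csv(inter, paths$interactions, progress = FALSE)
  readr::write_csv(
    plants[, c("accepted_name", "genus", "family", "origin", "woodiness",
               "native_regions")],
    paths$plants, progress = FALSE)
  readr::write_csv(occurrences, paths$occurrences, progress = FALSE)
  readr::write_csv(attr(plants, "region_centroids"), paths$region_centroids,
                   progress = FALSE)
  readr::write_csv(synonyms, paths$synonyms, progress = FALSE)
  readr::write_csv(first_records, paths$first_records, progress = FALSE)

  truth_json <- gen$truth
  truth_json$config <- unclass(truth_json$config)
  jsonlite::write_json(
    list(config = truth_json$config,
         centers = as.list(truth_json$centers),
         family_effects = truth_json$family_effects,
         plants = truth_json$plants,
         herbivores = truth_json$herbivores),
    paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = paths, plants = plants,
                 interactions = gen$interactions, truth = gen$truth))
}

# Regional first records: the species' true year, 0-2 later regional
# records, and a spurious early record for flagged species.
synth_first_records <- function(non, cfg) {
  if (nrow(non) == 0) {
    return(tibble::tibble(species = character(0), year = integer(0),
                          region = character(0)))
  }
  recs <- list(tibble::tibble(species = non$accepted_name,
                              year = non$intro_year,
                              region = "EUR-01"))
  extra_n <- rbinom(nrow(non), 2, 0.3)
  has_extra <- which(extra_n > 0)
  if (length(has_extra) > 0) {
    sp <- rep.int(non$accepted_name[has_extra], extra_n[has_extra])
    base <- rep.int(non$intro_year[has_extra], extra_n[has_extra])
    yr <- pmin(base + as.integer(round(runif(length(base), 1, 120))),
               cfg$year_max)
    recs <- c(recs, list(tibble::tibble(
      species = sp, year = yr,
      region = sprintf("EUR-%02d", sample.int(20, length(sp),
                                              replace = TRUE)))))
  }
  early <- which(non$pre1492)
  if (length(early) > 0) {
    recs <- c(recs, list(tibble::tibble(
      species = non$accepted_name[early],
      year = as.integer(round(runif(length(early), 1000, 1492))),
      region = "EUR-01")))
  }
  out <- dplyr::bind_rows(recs)
  out[order(out$species, out$year), ]
}
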