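#' Generate interactions and ground truth for a synthetic flora
#'
#' Draws each plant's microherbivore richness from the latent model
#' `log10(richness) = intercept(origin, woodiness) + beta * covariates +
#' family effect + noise`, rounds to the nearest integer and floors at 1
#' (only interacting plants are ever recorded, so zero-richness plants do
#' not exist), then assigns herbivore identities: an expected
#' `specialist_fraction` of herbivores receive exactly one host
#' (preferentially native), the rest receive multi-host sets, a share of
#' which is confined to a single plant family so that all four phagy
#' classes arise.
#'
#' @param plants Flora from [generate_flora()].
#' @param config The same [synthetic_config()].
#' @return List with `interactions` (tibble `plant_name`,
#'   `herbivore_name`), `truth` (per-plant latent and realised richness,
#'   family effects, per-herbivore host sets) of class `troph_truth`.
#' @export
generate_interactions <- function(plants, config) {
  stopifnot(inherits(config, "troph_config"))
  cfg <- validate_config(config)
  needed <- c("accepted_name", "origin", "woodiness_true", "family",
              "intro_year", "centroid_dist_km", "aoo_km2")
  missing_cols <- setdiff(needed, names(plants))
  if (length(missing_cols) > 0) {
    stop("plants table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  non <- plants$origin == "non-native"
  bad <- non & (is.na(plants$intro_year) | is.na(plants$centroid_dist_km) |
                  is.na(plants$aoo_km2))
  if (any(bad)) {
    stop("plants lacking covariates required by the latent model: ",
         paste(head(plants$accepted_name[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  set.seed(sub_seed(cfg$seed, 1L))

  centers <- config_centers(cfg)
  fams <- sort(unique(plants$family))
  u <- rnorm(length(fams), 0, cfg$sd_family)
  names(u) <- fams

  woody <- plants$woodiness_true == "woody"
  intercept <- ifelse(plants$origin == "native",
                      ifelse(woody, cfg$intercept_native_woody,
                             cfg$intercept_native_nonwoody),
                      ifelse(woody, cfg$intercept_nonnative_woody,
                             cfg$intercept_nonnative_nonwoody))
  eta <- intercept + u[plants$family]
  b_range <- ifelse(woody, cfg$beta_range_woody, cfg$beta_range_nonwoody)
  b_year <- ifelse(woody, cfg$beta_year_woody, cfg$beta_year_nonwoody)
  b_dist <- ifelse(woody, cfg$beta_dist_woody, cfg$beta_dist_nonwoody)
  eta[non] <- eta[non] +
    b_range[non] * (log10(plants$aoo_km2[non]) - centers[["log10_aoo"]]) +
    b_year[non] * (plants$intro_year[non] - centers[["intro_year"]]) +
    b_dist[non] * (plants$centroid_dist_km[non] -
                     centers[["centroid_dist_km"]])
  eta <- eta + rnorm(length(eta), 0, cfg$sd_resid)
  richness <- pmax(1L, as.integer(round(10^eta)))

  assign <- assign_herbivores(plants, richness, cfg)

  truth <- structure(list(
    config = cfg,
    centers = centers,
    family_effects = tibble::tibble(family = fams, effect = unname(u)),
    plants = tibble::tibble(accepted_name = plants$accepted_name,
                            latent_log10_richness = eta,
                            richness = richness),
    herbivores = assign$herbivores), class = "troph_truth")
  list(interactions = assign$interactions, truth = truth)
}

# Fill each plant's partner quota exactly. Slots (plant appearances) are
# first claimed by specialists with a native preference; multi-host
# herbivores then take distinct plants weighted by remaining capacity.
assign_herbivores <- function(plants, richness, cfg) {
  n_plants <- length(richness)
  N <- sum(richness)
  breadths <- draw_breadths(N, cfg)
  n_mono <- sum(breadths == 1L)

  remaining <- as.integer(richness)
  native <- plants$origin == "native"

  # specialist slots: native with probability specialist_native_pref
  mono_host <- integer(n_mono)
  if (n_mono > 0) {
    go_native <- runif(n_mono) < cfg$specialist_native_pref
    cap_nat <- sum(remaining[native])
    cap_non <- N - cap_nat
    k_nat <- min(sum(go_native), cap_nat)
    k_non <- min(n_mono - k_nat, cap_non)
    k_nat <- n_mono - k_non # spill back if non-native capacity ran out
    slot_pool <- function(idx, k) {
      if (k == 0) return(integer(0))
      slots <- rep.int(idx, remaining[idx])
      slots[sample.int(length(slots), k)]
    }
    picked <- c(slot_pool(which(native), k_nat),
                slot_pool(which(!native), k_non))
    mono_host <- picked
    tab <- tabulate(picked, nbins = n_plants)
    remaining <- remaining - tab
  }

  gen_b <- sort(breadths[breadths > 1L], decreasing = TRUE)
  gen_hosts <- vector("list", length(gen_b))
  extra_monos <- integer(0)
  if (length(gen_b) > 0) {
    fam_id <- as.integer(factor(plants$family))
    restricted <- runif(length(gen_b)) < cfg$p_family_restricted
    for (h in seq_along(gen_b)) {
      b <- gen_b[h]
      hosts <- integer(0)
      if (restricted[h]) {
        open_fam <- which(tabulate(fam_id[remaining > 0],
                                   nbins = max(fam_id)) > 0)
        if (length(open_fam) > 0) {
          wt <- tapply(remaining, fam_id, sum)
          f <- resample(open_fam, 1, prob = wt[open_fam])
          cand <- which(fam_id == f & remaining > 0)
          take <- min(b, length(cand))
          hosts <- resample(cand, take, prob = remaining[cand])
        }
      }
      need <- b - length(hosts)
      if (need > 0) {
        cand <- setdiff(which(remaining > 0), hosts)
        take <- min(need, length(cand))
        if (take > 0) {
          hosts <- c(hosts, resample(cand, take, prob = remaining[cand]))
        }
      }
      remaining[hosts] <- remaining[hosts] - 1L
      gen_hosts[[h]] <- hosts
    }
  }
  # capacity not absorbable under the distinct-host constraint becomes
  # additional monophagous herbivores (one per leftover slot)
  if (sum(remaining) > 0) {
    extra_monos <- rep.int(seq_len(n_plants), remaining)
  }

  host_sets <- c(gen_hosts, as.list(mono_host), as.list(extra_monos))
  n_herb <- length(host_sets)
  herb_names <- sprintf("herb%05d", seq_len(n_herb))
  edge_plant <- plants$accepted_name[unlist(host_sets, use.names = FALSE)]
  edge_herb <- rep.int(herb_names, lengths(host_sets))

  interactions <- tibble::tibble(plant_name = edge_plant,
                                 herbivore_name = edge_herb)
  herbivores <- tibble::tibble(
    herbivore_name = herb_names,
    n_hosts = lengths(host_sets))
  list(interactions = interactions, herbivores = herbivores)
}

# Host-count sequence summing exactly to n_slots: breadth 1 with
# probability specialist_fraction, else 2 + negative binomial.
draw_breadths <- function(n_slots, cfg) {
  out <- integer(0)
  total <- 0L
  while (total < n_slots) {
    chunk <- max(64L, ceiling((n_slots - total) / 3))
    mono <- runif(chunk) < cfg$specialist_fraction
    b <- ifelse(mono, 1L, 2L + rnbinom(chunk, size = 0.8, mu = 3))
    keep <- cumsum(b) <= (n_slots - total)
    out <- c(out, b[keep])
    total <- total + sum(b[keep])
    if (!all(keep)) { # close the gap and stop
      gap <- n_slots - total
      if (gap > 0) out <- c(out, gap)
      total <- n_slots
    }
  }
  as.integer(out)
}

# sample() that treats a length-1 x as a set, not 1:x
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}
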