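test_that("host breadth counts distinct host species", {
  x <- tibble::tibble(plant_name = c("P one", "P two", "P two", "P one"),
                      herbivore_name = c("h1", "h1", "h1", "h2"))
  hb <- host_breadth(x)
  expect_equal(hb$n_host_species[hb$herbivore_name == "h1"], 2L)
  expect_equal(hb$n_host_species[hb$herbivore_name == "h2"], 1L)
  s <- synth_small()
  hb2 <- host_breadth(s$interactions)
  m <- match(s$truth$herbivores$herbivore_name, hb2$herbivore_name)
  expect_equal(hb2$n_host_species[m], s$truth$herbivores$n_hosts)
})

test_that("phagy classes follow the narrow-to-broad rules", {
  expect_equal(classify_phagy(1, 1, 1), "monophagous")
  expect_equal(classify_phagy(3, 2, 1), "oligophagous")
  expect_equal(classify_phagy(2, 1, 1), "oligophagous")
  expect_equal(classify_phagy(6, 5, 1), "mesophagous")
  expect_equal(classify_phagy(6, 3, 3), "mesophagous")
  expect_equal(classify_phagy(4, 4, 4), "polyphagous")
  expect_equal(classify_phagy(10, 8, 5), "polyphagous")
  expect_error(classify_phagy(2, 3, 1), "inconsistent")
  expect_error(classify_phagy(1, 2, 1), "inconsistent")
  expect_error(classify_phagy(3, 2, 0), "inconsistent")
})

test_that("phagy classification is total and single-valued (enumeration)", {
  # every consistent (species, genera, families) triple up to 50 species
  grid <- expand.grid(s = 1:50, g = 1:50, f = 1:50)
  grid <- grid[grid$f <= grid$g & grid$g <= grid$s, ]
  grid <- grid[!(grid$s == 1 & (grid$g != 1 | grid$f != 1)), ]
  cls <- classify_phagy(grid$s, grid$g, grid$f)
  expect_true(all(cls %in% c("monophagous", "oligophagous", "mesophagous",
                             "polyphagous")))
  expect_identical(cls == "monophagous", grid$s == 1)
  # rule precedence: one-family profiles with few genera are oligophagous,
  # never mesophagous
  one_fam <- grid$f == 1 & grid$g <= 4 & grid$s > 1
  expect_true(all(cls[one_fam] == "oligophagous"))
})

test_that("per-plant mean breadth is the arithmetic mean of partners", {
  x <- tibble::tibble(plant_name = c("P one", "P one", "P two"),
                      herbivore_name = c("h1", "h2", "h3"))
  b <- tibble::tibble(herbivore_name = c("h1", "h2", "h3"),
                      n_host_species = c(10, 20, 1))
  out <- per_plant_mean_breadth(x, b)
  expect_equal(out$mean_breadth[out$plant_name == "P one"], 15)
  expect_equal(out$mean_breadth[out$plant_name == "P two"], 1)
  expect_error(per_plant_mean_breadth(x, b[1:2, ]), "without a host breadth")
  s <- synth_small()
  hb <- host_breadth(s$interactions)
  got <- per_plant_mean_breadth(s$interactions, hb)
  # brute-force recomputation for a handful of plants
  for (p in head(got$plant_name, 5)) {
    partners <- unique(s$interactions$herbivore_name[
      s$interactions$plant_name == p])
    expect_equal(got$mean_breadth[got$plant_name == p],
                 mean(hb$n_host_species[match(partners, hb$herbivore_name)]))
  }
})

test_that("breadth is monotone under removing a plant", {
  s <- synth_small()
  hb <- host_breadth(s$interactions)
  drop <- s$flora$accepted_name[which.max(s$truth$plants$richness)]
  sub <- s$interactions[s$interactions$plant_name != drop, ]
  hb2 <- host_breadth(sub)
  m <- match(hb2$herbivore_name, hb$herbivore_name)
  expect_true(all(hb2$n_host_species <= hb$n_host_species[m]))
})

test_that("integration filter applies growth-form thresholds strictly", {
  plants <- tibble::tibble(
    accepted_name = paste("p", 1:6),
    origin = c("native", rep("non-native", 5)),
    woodiness = c("non-woody", "woody", "non-woody", "woody", "non-woody",
                  "unknown"),
    aoo_km2 = c(NA, 3e5, 3e5, 270000, 1.2e6, 5e6))
  out <- integration_filter(plants)
  expect_true("p 1" %in% out$accepted_name)   # natives untouched
  expect_true("p 2" %in% out$accepted_name)   # woody above 270k
  expect_false("p 3" %in% out$accepted_name)  # non-woody below 1.1M
  expect_false("p 4" %in% out$accepted_name)  # exactly at threshold: dropped
  expect_true("p 5" %in% out$accepted_name)
  expect_false("p 6" %in% out$accepted_name)  # unknown woodiness
  expect_equal(attr(out, "n_dropped"), 3)
})

test_that("composition proportions are exact and sum to one", {
  x <- tibble::tibble(plant_name = c("P one", "P one"),
                      herbivore_name = c("h1", "h2"))
  prof <- tibble::tibble(herbivore_name = c("h1", "h2"),
                         phagy = c("monophagous", "polyphagous"))
  plants <- tibble::tibble(accepted_name = "P one", origin = "native",
                           woodiness = "woody")
  out <- composition_summary(x, prof, plants)
  expect_equal(out$proportion[out$phagy == "monophagous"], 0.5)
  expect_equal(out$proportion[out$phagy == "polyphagous"], 0.5)
  expect_equal(sum(out$proportion), 1)
})

test_that("interaction-count weighting reproduces the hand calculation", {
  x <- tibble::tibble(
    plant_name = c("P one", "P two", "P two", "P two"),
    herbivore_name = c("h1", "h1", "h2", "h3"))
  prof <- tibble::tibble(
    herbivore_name = c("h1", "h2", "h3"),
    phagy = c("monophagous", "polyphagous", "polyphagous"))
  plants <- tibble::tibble(accepted_name = c("P one", "P two"),
                           origin = "native", woodiness = "woody")
  out <- composition_summary(x, prof, plants, weights = "interactions")
  # P one: (1,0) weight 1; P two: (1/3, 2/3) weight 3 -> mono (1+1)/4
  expect_equal(out$proportion[out$phagy == "monophagous"], 0.5)
  expect_equal(out$proportion[out$phagy == "polyphagous"], 0.5)
  unw <- composition_summary(x, prof, plants)
  expect_equal(unw$proportion[unw$phagy == "monophagous"], 2 / 3)
})

test_that("all-specialist networks give a pure monophagous composition", {
  cfg <- small_config(seed = 17, specialist_fraction = 1)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  prof <- herbivore_profiles(gi$interactions, fl)
  out <- composition_summary(gi$interactions, prof, fl)
  expect_true(all(out$proportion[out$phagy == "monophagous"] == 1))
  expect_true(all(out$proportion[out$phagy != "monophagous"] == 0))
})

test_that("residence-time bins partition non-natives by 50-year windows", {
  s <- synth_small()
  prof <- herbivore_profiles(s$interactions, s$flora)
  plants <- s$flora
  plants$richness <- s$truth$plants$richness[
    match(plants$accepted_name, s$truth$plants$accepted_name)]
  out <- composition_summary(s$interactions, prof, plants,
                             by = "residence_bin", reference_year = 2025)
  expect_true(all(out$residence_bin %% 50 == 0))
  sums <- tapply(out$proportion, out$residence_bin, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
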