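test_that("outlier screening follows the k-SD rule with the candidate included", {
  flat <- nectar_table(rep("A", 5), paste0("s", 1:5), rep("glucose", 5),
                       rep(1, 5))
  out <- remove_outliers(flat, k = 2)
  expect_equal(nrow(out$report), 0)  # SD 0: no finite z exceeds

  v <- c(1, 1, 1, 1, 100)
  spike <- nectar_table(rep("A", 5), paste0("s", 1:5), rep("glucose", 5), v)
  # leave-one-out oracle arithmetic: the remainder (1,1,1,1) has SD 0, so
  # the spike's deviation exceeds k * 0 at any k; the non-spikes are judged
  # against remainders with SD ~ 49.5 and deviation ~ 24.75, z ~ -0.5
  z_loo <- (v[1] - mean(v[-1])) / sd(v[-1])
  expect_equal(z_loo, -0.5, tolerance = 1e-12)
  rem <- remove_outliers(spike, k = 4)
  expect_equal(rem$report$value, 100)
  expect_true(is.infinite(rem$report$z_score))
  expect_equal(nrow(rem$samples), 4)
  # the legitimate values are never removed, even at a tight k
  expect_equal(remove_outliers(spike, k = 1)$report$value, 100)

  # groups smaller than 3 are left unscreened
  tiny <- nectar_table(rep("A", 2), c("s1", "s2"), rep("glucose", 2),
                       c(1, 1000))
  expect_equal(nrow(remove_outliers(tiny, k = 1)$report), 0)
})

test_that("an injected 10-SD spike is exactly what k = 4 removes", {
  profiles <- expand.grid(species = paste0("sp", 1:6),
                          compound = c("glucose", "proline"),
                          stringsAsFactors = FALSE)
  profiles$mean <- 10
  profiles$sd <- 1
  sim <- simulate_nectar_panel(profiles, n_reps = 13, seed = 5)
  x <- sim$samples
  i <- which(x$species == "sp3" & x$compound == "proline")[1]
  grp <- x$species == "sp3" & x$compound == "proline"
  x$concentration[i] <- mean(x$concentration[grp]) +
    10 * sd(x$concentration[grp])
  rem <- remove_outliers(x, k = 4)
  expect_equal(nrow(rem$report), 1)
  expect_equal(rem$report$sample_id, x$sample_id[i])
  expect_equal(rem$report$compound, "proline")
})

make_labels <- function() {
  c(sp1 = "female_associated", sp2 = "female_associated",
    sp3 = "female_associated", sp4 = "female_associated",
    sp5 = "male_associated", sp6 = "male_associated")
}

panel_profiles <- function(mean = 10, sd = 1, compound = "glucose") {
  data.frame(species = paste0("sp", 1:6), compound = compound,
             mean = mean, sd = sd, stringsAsFactors = FALSE)
}

test_that("group contrast recovers a known shift with high precision", {
  sim <- simulate_nectar_panel(panel_profiles(mean = 10, sd = 0.1),
                               n_reps = 13, shift = 2,
                               female_species = paste0("sp", 1:4), seed = 31)
  r <- group_contrast(sim$samples, make_labels(), "glucose")
  expect_gt(r$estimate, 1.9)
  expect_lt(r$estimate, 2.1)
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$f_stat, (r$estimate / r$se)^2)
  expect_equal(r$den_df_pooled, 6 * 12)
})

test_that("contrast invariances: location shift and label swap", {
  sim <- simulate_nectar_panel(panel_profiles(mean = 12, sd = 2),
                               n_reps = 8, seed = 8)
  lab <- make_labels()
  r <- group_contrast(sim$samples, lab, "glucose")

  shifted <- sim$samples
  shifted$concentration <- shifted$concentration + 100
  r2 <- group_contrast(shifted, lab, "glucose")
  expect_equal(r2$estimate, r$estimate)
  expect_equal(r2$f_stat, r$f_stat)

  swapped <- ifelse(lab == "female_associated", "male_associated",
                    "female_associated")
  names(swapped) <- names(lab)
  r3 <- group_contrast(sim$samples, swapped, "glucose")
  expect_equal(r3$estimate, -r$estimate)
  expect_equal(r3$f_stat, r$f_stat)
})

test_that("contrast matches a heterogeneous-variance gls fit", {
  set.seed(91)
  profiles <- panel_profiles(mean = 10, sd = 1)
  profiles$sd <- c(0.5, 1, 2, 4, 1, 3)  # strong heteroscedasticity
  sim <- simulate_nectar_panel(profiles, n_reps = 13, shift = 1.5,
                               female_species = paste0("sp", 1:4), seed = 91)
  lab <- make_labels()
  r <- group_contrast(sim$samples, lab, "glucose")

  fit <- nlme::gls(concentration ~ 0 + species, data = sim$samples,
                   weights = nlme::varIdent(form = ~ 1 | species))
  co <- stats::coef(fit)[paste0("species", paste0("sp", 1:6))]
  w <- c(rep(1 / 4, 4), rep(-1 / 2, 2))
  expect_equal(r$estimate, unname(sum(w * co)), tolerance = 1e-6)
  se_gls <- sqrt(drop(t(w) %*% stats::vcov(fit) %*% w))
  # gls uses ML-flavoured variance weights; agreement is close, not exact
  expect_equal(r$se, unname(se_gls), tolerance = 0.05)
})

test_that("a species with one replicate is excluded with a warning", {
  sim <- simulate_nectar_panel(panel_profiles(), n_reps = 13, seed = 3)
  x <- sim$samples
  x <- x[!(x$species == "sp1" & x$sample_id != "sp1_1"), ]
  expect_warning(r <- group_contrast(x, make_labels(), "glucose"),
                 "single replicate")
  expect_equal(r$n_species[["female"]], 3L)
  # dropping below two species per group is an error
  y <- sim$samples[!sim$samples$species %in% c("sp1", "sp2", "sp3"), ]
  expect_error(group_contrast(y, make_labels(), "glucose"),
               ">= 2 species")
})

test_that("null panels give approximately uniform p-values", {
  set.seed(47)
  lab <- make_labels()
  p <- vapply(1:300, function(i) {
    sim <- simulate_nectar_panel(panel_profiles(mean = 10, sd = 1),
                                 n_reps = 13)
    group_contrast(sim$samples, lab, "glucose")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})

test_that("Bonferroni families scale alpha by family size", {
  mk <- function(p) structure(list(p_value = p, alpha_adjusted = NA,
                                   significant = NA),
                              class = "contrast_result")
  fam5 <- bonferroni_family(rep(list(mk(0.011)), 5))
  expect_equal(fam5[[1]]$alpha_adjusted, 0.01)
  expect_false(fam5[[1]]$significant)

  fam4 <- bonferroni_family(rep(list(mk(0.011)), 4))
  expect_equal(fam4[[1]]$alpha_adjusted, 0.0125)
  expect_true(fam4[[1]]$significant)

  fam1 <- bonferroni_family(list(mk(0.04)))
  expect_equal(fam1[[1]]$alpha_adjusted, 0.05)
  expect_true(fam1[[1]]$significant)
  expect_error(bonferroni_family(list()), "empty")

  # significant <=> p < alpha_adjusted across a family
  fam <- bonferroni_family(lapply(c(0.001, 0.02, 0.9), mk))
  for (r in fam) expect_equal(r$significant, r$p_value < r$alpha_adjusted)
})

test_that("sparsely detected compounds are excluded from families", {
  sim <- simulate_nectar_panel(
    rbind(panel_profiles(compound = "glucose"),
          panel_profiles(compound = "fructose"),
          panel_profiles(compound = "phenylalanine")),
    n_reps = 13, seed = 55)
  x <- sim$samples
  # phenylalanine undetected in 60% of replicates
  phe <- which(x$compound == "phenylalanine")
  x <- x[-phe[seq_len(round(0.6 * length(phe)))], ]
  res <- suppressMessages(nectar_contrasts(
    x, make_labels(),
    families = list(sugars = c("glucose", "fructose", "phenylalanine"))
  ))
  expect_equal(res$excluded_compounds, "phenylalanine")
  expect_named(res$contrasts$sugars, c("glucose", "fructose"))
  expect_equal(res$contrasts$sugars$glucose$alpha_adjusted, 0.025)
})

test_that("replicate design supports unequal replication", {
  reps <- c(sp1 = 13, sp2 = 13, sp3 = 13, sp4 = 13, sp5 = 13, sp6 = 8)
  sim <- simulate_nectar_panel(panel_profiles(sd = 0), n_reps = reps,
                               seed = 2)
  tab <- table(sim$samples$species)
  expect_equal(unname(tab[paste0("sp", 1:6)]), c(13L, 13L, 13L, 13L, 13L, 8L),
               ignore_attr = TRUE)
  # SD 0 panels are exactly constant at the species mean
  expect_true(all(sim$samples$concentration == 10))
})
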