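test_that("the shipped region map has the expected structure", {
  map <- load_region_map()
  expect_equal(nrow(map), 68)
  expect_equal(length(unique(map$region)), 10)
  counts <- table(map$lobe, map$hemisphere)
  expect_equal(counts["frontal", "left"], 11)
  expect_equal(counts["frontal", "right"], 11)
  expect_equal(counts["parietal", "left"], 5)
  expect_equal(counts["occipital", "left"], 4)
  expect_equal(counts["cingulate", "left"], 4)
  expect_equal(counts["temporal", "left"], 10)  # incl. insula
  # mirror symmetry
  expect_true(all(counts[, "left"] == counts[, "right"]))
})

test_that("override files are validated", {
  map <- load_region_map()
  bad <- map[-1, ]
  path <- tempfile(fileext = ".tsv")
  write.table(bad[c("micro", "hemisphere", "lobe")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_region_map(path), "68")

  dup <- map
  dup$micro[2] <- dup$micro[1]
  write.table(dup[c("micro", "hemisphere", "lobe")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_region_map(path), "duplicate")
})

test_that("macro aggregation averages valid parcels only", {
  map <- load_region_map()
  lf <- map$micro[map$region == "frontal_left"]
  est <- data.frame(micro = lf, paf_hz = c(9.8, 9.8, 9.8,
                                           rep(NA, length(lf) - 3)))
  agg <- aggregate_macro(est, map)
  expect_equal(agg$paf_hz, 9.8)
  expect_equal(agg$n_valid_micro, 3)
  expect_equal(agg$n_total_micro, 11)

  est2 <- data.frame(micro = lf[1:2], paf_hz = c(9, 10))
  expect_equal(aggregate_macro(est2, map)$paf_hz, 9.5)

  # all absent -> missing record, not a dropped row
  est3 <- data.frame(micro = lf, paf_hz = NA_real_)
  agg3 <- aggregate_macro(est3, map)
  expect_true(is.na(agg3$paf_hz))
  expect_equal(agg3$n_valid_micro, 0)

  expect_error(aggregate_macro(data.frame(micro = "nowhere", paf_hz = 9),
                               map), "unknown")
})

test_that("aggregation is permutation-invariant and bounded", {
  map <- load_region_map()
  set.seed(2)
  for (i in 1:10) {
    est <- micro_table(map, paf = runif(68, 8, 12))
    est$paf_hz[sample(68, 20)] <- NA
    a1 <- aggregate_macro(est[c("micro", "paf_hz")], map)
    a2 <- aggregate_macro(est[sample(68), c("micro", "paf_hz")], map)
    a2 <- a2[match(a1$region, a2$region), ]
    expect_equal(a1$paf_hz, a2$paf_hz)
    for (r in a1$region) {
      vals <- est$paf_hz[map$region[match(est$micro, map$micro)] == r]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        v <- a1$paf_hz[a1$region == r]
        expect_gte(v, min(vals))
        expect_lte(v, max(vals))
      }
    }
  }
})

test_that("macro-level completeness is at least micro-level validity", {
  # averaging can only rescue subjects: a macro-region is present if any
  # parcel is, so the per-subject macro present-rate dominates the
  # parcel-level validity proportion
  map <- load_region_map()
  set.seed(5)
  for (rep in 1:5) {
    subj <- sprintf("S%02d", 1:12)
    est <- do.call(rbind, lapply(subj, function(s) {
      e <- micro_table(map, paf = runif(68, 8, 12), subject = s)
      e$paf_hz[runif(68) < 0.6] <- NA
      e
    }))
    agg <- aggregate_macro(est[c("subject", "micro", "paf_hz")], map)
    for (r in unique(map$region)) {
      micro_rate <- mean(!is.na(est$paf_hz[
        map$region[match(est$micro, map$micro)] == r]))
      macro_rate <- mean(!is.na(agg$paf_hz[agg$region == r]))
      expect_gte(macro_rate, micro_rate)
    }
  }
})

test_that("validity proportions use the full parcel denominator", {
  expect_equal(validity_proportion(319, 11, 29), 100)
  expect_equal(validity_proportion(10, 2, 10), 50)
  expect_equal(validity_proportion(0, 4, 5), 0)
  expect_error(validity_proportion(30, 2, 10))  # more present than cells

  map <- load_region_map()
  est <- do.call(rbind, lapply(sprintf("S%02d", 1:29), function(s)
    micro_table(map, paf = 10, subject = s, condition = "EO")))
  vt <- validity_table(est, map)
  lf <- vt[vt$region == "frontal_left", ]
  expect_equal(lf$n_micro * lf$n_subjects, 319)
  expect_equal(lf$validity_pct, 100)
})
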