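test_that("connection score matches hand-enumerated values", {
  profile <- c(g1 = 1, g2 = 4, g3 = -3, g4 = 2)
  sig <- query_signature(c("g1", "g3"), c(1, -1))
  # raw = 1*1 + (-1)*(-3) = 4; max = 4 + 3 = 7
  expect_equal(connection_score(sig, profile), 4 / 7)
  expect_equal(connection_score(sig, profile),
               naive_cscore(c("g1", "g3"), c(1, -1), profile))

  # signature of the strongest genes with matching signs scores exactly 1
  strongest <- names(sort(abs(profile), decreasing = TRUE))[1:2]
  match_sig <- query_signature(strongest, sign(profile[strongest]))
  expect_equal(connection_score(match_sig, profile), 1)
  flip_sig <- query_signature(strongest, -sign(profile[strongest]))
  expect_equal(connection_score(flip_sig, profile), -1)

  expect_error(connection_score(query_signature("zz", 1), profile),
               "absent")
})

test_that("cscore ignores genes outside the signature", {
  set.seed(2)
  profile <- random_profile(10)
  sig <- query_signature(c("g001", "g005"), c(1, -1))
  base <- connection_score(sig, profile)
  # permute the signed ranks of all non-signature genes
  others <- setdiff(names(profile), sig$gene_id)
  profile2 <- profile
  profile2[others] <- profile[sample(others)]
  expect_equal(connection_score(sig, profile2), base)
})

test_that("exhaustive p-values are exact and Monte-Carlo agrees", {
  profile <- c(g1 = 1, g2 = 4, g3 = -3, g4 = 2)
  sig <- query_signature("g2", 1)  # cscore = 1
  expect_equal(profile_p_value(sig, profile, mode = "exhaustive"), 1 / 8)
  expect_equal(profile_p_value(sig, profile, mode = "exhaustive"),
               brute_force_p(profile, 1, 1, "upper"))

  # observed score 0 sits at the median of the symmetric null
  set.seed(5)
  prof <- random_profile(30)
  zero_sig <- query_signature(c("g001", "g002"), c(1, 1))
  # build a profile where those two genes cancel exactly
  prof[c("g001", "g002")] <- c(7, -7)
  expect_equal(connection_score(zero_sig, prof), 0)
  p0 <- profile_p_value(zero_sig, prof, n_null = 4000, seed = 9,
                        mode = "montecarlo")
  expect_equal(p0, 0.5, tolerance = 0.05)

  # Monte-Carlo vs exhaustive on random small instances
  set.seed(31)
  for (case in 1:20) {
    prof <- random_profile(6)
    genes <- sample(names(prof), 2)
    sig <- query_signature(genes, sample(c(-1, 1), 2, TRUE))
    pe <- profile_p_value(sig, prof, mode = "exhaustive")
    pm <- profile_p_value(sig, prof, n_null = 3000, seed = case,
                          mode = "montecarlo")
    se <- sqrt(pe * (1 - pe) / 3000)
    expect_lt(abs(pm - pe), 3 * se + 2 / 3001)
  }
})

test_that("sign flips negate the score and swap the p-value tail", {
  set.seed(13)
  for (case in 1:50) {
    prof <- random_profile(8)
    m <- sample(1:3, 1)
    genes <- sample(names(prof), m)
    signs <- sample(c(-1, 1), m, TRUE)
    sig <- query_signature(genes, signs)
    neg <- query_signature(genes, -signs)
    expect_equal(connection_score(neg, prof), -connection_score(sig, prof))
    pu <- profile_p_value(sig, prof, mode = "exhaustive", tail = "upper")
    pl <- profile_p_value(neg, prof, mode = "exhaustive", tail = "lower")
    expect_equal(pu, pl)
  }
})

test_that("compound aggregation averages replicates and tightens the null", {
  set.seed(17)
  N <- 40
  universe <- sprintf("g%03d", 1:N)
  prof <- sample(c(-1L, 1L), N, TRUE) * sample.int(N)
  # one compound with a single profile, one with the same profile 3 times
  ranks <- cbind(prof, prof, prof, prof)
  meta <- data.frame(compound = c("solo", "trip", "trip", "trip"),
                     replicate_id = c("r1", "r1", "r2", "r3"))
  db <- reference_db(universe, ranks, meta)
  sig <- query_signature(universe[1:4], c(1, -1, 1, 1))
  res <- map_signature(sig, db, n_null = 3000, seed = 19)
  solo <- res[res$compound == "solo", ]
  trip <- res[res$compound == "trip", ]
  named_prof <- setNames(as.numeric(prof), universe)
  expect_equal(solo$cscore, connection_score(sig, named_prof))
  expect_equal(trip$cscore, solo$cscore)
  # identical replicates share the same null, so z agrees exactly
  expect_equal(trip$z_score, solo$z_score)

  # independent replicates tighten the null: plant the same signature at
  # the top ranks (reversed) of 3 independent profiles and of 1 profile;
  # same cscore, but the 3-replicate compound's |z| is larger
  m <- 4
  plant <- function() {
    col <- integer(N)
    col[1:m] <- -sig$sign * sample((N - m + 1):N)
    col[(m + 1):N] <- sample(c(-1L, 1L), N - m, TRUE) * sample.int(N - m)
    col
  }
  ranks_i <- cbind(plant(), plant(), plant(), plant())
  db_i <- reference_db(universe, ranks_i,
                       data.frame(compound = c("solo", "ind", "ind", "ind"),
                                  replicate_id = c("r1", "r1", "r2", "r3")))
  r <- map_signature(sig, db_i, n_null = 3000, seed = 23)
  expect_equal(r$cscore[r$compound == "ind"], -1)
  expect_equal(r$cscore[r$compound == "solo"], -1)
  expect_gt(abs(r$z_score[r$compound == "ind"]),
            abs(r$z_score[r$compound == "solo"]))
  expect_equal(attr(r, "Nc"), 2)
})

test_that("significance filtering applies the Efp/Nc threshold and direction", {
  res <- structure(
    data.frame(compound = c("a", "b", "c", "d"),
               replicate_count = 1L,
               cscore = c(-0.144, 0.2, -0.3, -0.1),
               p_value = c(5.0e-06, 1e-05, 0.01, 7.0e-04),
               z_score = c(-5.87, 4.2, -1.2, -3.1),
               direction = c("negative", "positive", "negative", "negative"),
               stringsAsFactors = FALSE),
    class = c("connection_results", "data.frame"), Nc = 1309)
  hits <- significant_connections(res, Efp = 1)
  # threshold 1/1309 ~ 7.639e-4 keeps a (p=5e-6, negative) and d (7e-4)
  expect_equal(sort(hits$compound), c("a", "d"))
  expect_equal(attr(hits, "Ns"), 2)
  expect_equal(attr(hits, "threshold"), 1 / 1309)
  # positive compound excluded despite a tiny p-value
  expect_false("b" %in% hits$compound)
  both <- significant_connections(res, Efp = 1, direction_filter = "both")
  expect_true("b" %in% both$compound)
  none <- significant_connections(res[0, ], Efp = 1, Nc = 1309)
  expect_equal(attr(none, "Ns"), 0)
})

test_that("reference databases round-trip through the long TSV format", {
  set.seed(29)
  gen <- generate_reference_db(sprintf("g%03d", 1:25), n_compounds = 4,
                               replicates_range = c(1, 2),
                               n_inhibitors = 0, seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_reference_db(gen$db, path)
  back <- read_reference_db(path)
  expect_equal(back$universe, gen$db$universe)
  expect_equal(back$Nc, gen$db$Nc)
  # same profiles under (compound, replicate) keys
  key <- function(db) paste(db$profile_meta$compound, db$profile_meta$replicate_id)
  o1 <- order(key(gen$db))
  o2 <- order(key(back))
  expect_equal(unname(back$ranks[, o2]), unname(gen$db$ranks[, o1]))
  expect_error(subset_reference_db(gen$db, "nope"), "unknown compound")
})
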