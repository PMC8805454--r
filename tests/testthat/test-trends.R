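test_that("national rescaling follows the comparator ratio", {
  expect_equal(adjust_total(100, 50000, 100), 50000)
  expect_equal(adjust_total(40, 50000, 80), 25000)
  expect_equal(adjust_total(0, 50000, 80), 0)
  expect_error(adjust_total(40, 50000, 0), "unusable comparator")
})

test_that("state apportionment floors the share-weighted product", {
  expect_equal(apportion_state(25000, 50, 100, 1e6, 1e7), 1250L)
  expect_equal(apportion_state(123.7, 100, 100, 5, 5), 123L)
  expect_equal(apportion_state(10, 1, 100, 1, 1000), 0L)
  expect_equal(apportion_state(10, 0, 0, 1, 1000), 0L)
  expect_error(apportion_state(10, 5, 0, 1, 1000), "inconsistent")
})

test_that("rescaling is linear in the comparator volume with floor bound", {
  set.seed(41)
  for (i in 1:20) {
    nt <- runif(1, 1, 100); sv <- sample(c(5e4, 1e5, 2e5), 1)
    cn <- runif(1, 1, 100)
    expect_equal(adjust_total(nt, 2 * sv, cn), 2 * adjust_total(nt, sv, cn))
    ns <- runif(1, 0, 100); ps <- runif(1, 1e5, 1e7); pt <- 3e8
    tot <- adjust_total(nt, sv, cn)
    pre <- tot * ns / nt * ps / pt
    got <- apportion_state(tot, ns, nt, ps, pt)
    expect_true(got <= pre + 1e-6 && pre - got < 1)
  }
})

test_that("comparator tiers floor to the published tier values", {
  expect_equal(comparator_tier_floor(c(50000, 73000, 99999, 100000)),
               c(50000, 50000, 50000, 100000))
  expect_error(comparator_tier_floor(100), "below the lowest")
})

test_that("the 17 terms partition into the published clusters", {
  cl <- mh_term_clusters()
  expect_equal(lengths(cl[c("Depression", "Anxiety", "Nonspecific")]),
               c(Depression = 7L, Anxiety = 6L, Nonspecific = 4L))
  expect_equal(sort(cl$All),
               sort(unique(c(cl$Depression, cl$Anxiety, cl$Nonspecific))))
  expect_equal(length(cl$All), 17L)
  expect_equal(length(intersect(cl$Depression, cl$Anxiety)), 0L)
  expect_equal(length(intersect(cl$Depression, cl$Nonspecific)), 0L)
  expect_equal(length(intersect(cl$Anxiety, cl$Nonspecific)), 0L)
})

test_that("cluster sums pool term counts and satisfy the partition identity", {
  cl <- mh_term_clusters()
  counts <- tidyr::expand_grid(state = c("MA", "TX"),
                               date = as.Date("2020-03-24") + 0:1,
                               term = cl$All)
  counts$count <- 1L
  sums <- cluster_sums(counts)
  one <- sums[sums$state == "MA" & sums$date == as.Date("2020-03-24"), ]
  expect_equal(setNames(one$count, one$cluster),
               c(All = 17L, Depression = 7L, Anxiety = 6L,
                 Nonspecific = 4L))

  set.seed(42)
  counts$count <- rnbinom(nrow(counts), mu = 8, size = 3)
  sums <- tidyr::pivot_wider(cluster_sums(counts),
                             names_from = "cluster",
                             values_from = "count")
  expect_true(all(sums$All ==
                    sums$Depression + sums$Anxiety + sums$Nonspecific))

  zero <- counts; zero$count <- 0L
  expect_true(all(cluster_sums(zero)$count == 0))
})

test_that("a partial day errors while a wholly absent day is just absent", {
  cl <- mh_term_clusters()
  counts <- tidyr::expand_grid(state = "MA",
                               date = as.Date("2020-03-24") + 0:1,
                               term = cl$All)
  counts$count <- 1L
  absent <- counts[!(counts$date == as.Date("2020-03-25")), ]
  expect_equal(nrow(cluster_sums(absent)), 4)  # 1 day x 4 clusters
  partial <- counts[-1, ]                      # drop one term on one day
  expect_error(cluster_sums(partial), "partial day")
})

test_that("estimation drops unusable-comparator days with a message", {
  pop <- tibble::tibble(state = c("MA", "TX"),
                        population = c(7e6, 29e6))
  trends <- tidyr::expand_grid(date = as.Date("2020-03-24") + 0:1,
                               term = "anxiety", state = c("MA", "TX"))
  trends$mh_norm_state <- c(50, 100, 40, 80)
  trends$mh_norm_total <- c(60, 60, 50, 50)
  trends$comp_norm_total <- c(80, 80, 0, 0)
  trends$comp_search_volume <- 50000
  expect_message(got <- estimate_state_counts(trends, pop),
                 "1 day\\(s\\) with unusable comparator")
  expect_equal(unique(got$date), as.Date("2020-03-24"))
  expect_equal(attr(got, "n_dropped_days"), 1L)
  # hand-check one row: 60*50000/80 = 37500; *50/60 * 7/36
  expect_equal(got$count[got$state == "MA"],
               as.integer(floor(37500 * 50 / 60 * 7e6 / 36e6)))
})

test_that("trends and population readers accept long and wide dialects", {
  long <- tempfile(fileext = ".csv")
  writeLines(c(
    "date,term,state,mh_norm_state,mh_norm_total,comp_norm_total,comp_search_volume",
    "2020-03-24,anxiety,MA,50,60,80,50000"), long)
  got <- read_trends(long)
  expect_equal(got$mh_norm_state, 50)

  wide <- tempfile(fileext = ".csv")
  writeLines(c(
    "date,term,mh_norm_total,comp_norm_total,comp_search_volume,norm_MA,norm_TX",
    "2020-03-24,anxiety,60,80,50000,50,100"), wide)
  gotw <- read_trends(wide)
  expect_equal(nrow(gotw), 2)
  expect_equal(sort(gotw$state), c("MA", "TX"))

  pops <- tempfile(fileext = ".csv")
  writeLines(c("state,population", "MA,7000000", "TX,29000000"), pops)
  expect_equal(read_populations(pops)$population, c(7e6, 29e6))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("state,population", "MA,7000000", "MA,1"), bad)
  expect_error(read_populations(bad), "duplicate")
})
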