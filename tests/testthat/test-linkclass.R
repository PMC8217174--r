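# Link taxonomy: nature precedence, persistence, counts, normalization.

regions4 <- c("M1", "Put", "SN", "Tal")

test_that("nature follows the detection precedence rules", {
  pc <- make_graph(link_df(list("M1", "Put", 0, 0.9, 0.005)),
                   "PC", "resting", regions4)
  gp <- make_graph(link_df(list("M1", "Put", 0, 0.5, 0.005),
                           list("Put", "SN", 1, 0.3, 0.005)),
                   "GPDC", "resting", regions4)
  cmi <- make_graph(link_df(list("SN", "Tal", 0, 0.2, 0.005)),
                    "CMIknn", "resting", regions4)
  tab <- classify_nature(list(PC = pc, GPDC = gp, CMIknn = cmi))
  nature_of <- function(s, t, l) {
    tab$nature[tab$source == s & tab$target == t & tab$lag == l]
  }
  # significant under PC and GPDC -> linear
  expect_equal(nature_of("M1", "Put", 0), "linear")
  # GPDC only -> non-linear
  expect_equal(nature_of("Put", "SN", 1), "non-linear")
  # CMIknn only -> complex
  expect_equal(nature_of("SN", "Tal", 0), "complex")
  # timing is determined by the lag
  expect_equal(tab$timing[tab$lag == 0][1], "instantaneous")
  expect_equal(tab$timing[tab$lag == 1][1], "single-delayed")
  # nature classes partition the detected links
  expect_true(all(tab$nature %in% c("linear", "non-linear", "complex")))
  expect_true(all(nchar(tab$methods) > 0))
})

test_that("PC significance alone still means linear", {
  pc <- make_graph(link_df(list("Put", "SN", 0, 0.4, 0.008)),
                   "PC", "resting", regions4)
  gp <- make_graph(empty_links(), "GPDC", "resting", regions4)
  tab <- classify_nature(list(PC = pc, GPDC = gp))
  expect_equal(tab$nature, "linear")
})

test_that("lag-0 links match regardless of orientation", {
  pc <- make_graph(link_df(list("Put", "M1", 0, 0.9, 0.005)),
                   "PC", "resting", regions4)
  cmi <- make_graph(link_df(list("M1", "Put", 0, 0.2, 0.005)),
                    "CMIknn", "resting", regions4)
  tab <- classify_nature(list(PC = pc, CMIknn = cmi))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$nature, "linear")
  expect_equal(tab$methods, "PC,CMIknn")
})

test_that("condition mismatch across method graphs is rejected", {
  pc <- make_graph(empty_links(), "PC", "resting", regions4)
  gp <- make_graph(empty_links(), "GPDC", "motor", regions4)
  expect_error(classify_nature(list(PC = pc, GPDC = gp)),
               "different conditions")
})

test_that("persistence is permanent iff significant in every condition", {
  mk <- function(cond, links) {
    classify_nature(list(PC = make_graph(links, "PC", cond, regions4)))
  }
  tabs <- list(
    resting = mk("resting", link_df(list("M1", "Put", 0),
                                    list("Put", "SN", 1))),
    motor = mk("motor", link_df(list("M1", "Put", 0),
                                list("SN", "Tal", 2)))
  )
  pers <- classify_persistence(tabs)
  get <- function(s, t, l) {
    pers$persistence[pers$source == s & pers$target == t & pers$lag == l]
  }
  expect_equal(get("M1", "Put", 0), "permanent")
  expect_equal(get("Put", "SN", 1), "resting-only")
  expect_equal(get("SN", "Tal", 2), "motor-only")
  # symmetric in condition order
  pers2 <- classify_persistence(rev(tabs))
  m <- match(paste(pers$source, pers$target, pers$lag),
             paste(pers2$source, pers2$target, pers2$lag))
  expect_equal(pers$persistence, pers2$persistence[m])
})

test_that("counts are exhaustive and consistent across dimensions", {
  tab <- classify_nature(list(
    PC = make_graph(link_df(list("M1", "Put", 0), list("Put", "SN", 1),
                            list("M1", "SN", 0)), "PC", "resting", regions4),
    CMIknn = make_graph(link_df(list("SN", "Tal", 2)), "CMIknn", "resting",
                        regions4)))
  counts <- tabulate_counts(tab)
  expect_equal(sum(counts$n), nrow(tab))
  expect_equal(attr(counts, "total"), nrow(tab))
  by_timing <- tapply(counts$n, counts$timing, sum)
  by_nature <- tapply(counts$n, counts$nature, sum)
  expect_equal(sum(by_timing), sum(by_nature))
  # empty input gives all-zero counts
  empty <- tabulate_counts(classify_nature(list(
    PC = make_graph(empty_links(), "PC", "resting", regions4))))
  expect_equal(attr(empty, "total"), 0L)
})

test_that("statistic normalization preserves sign and order, strongest maps to 1", {
  df <- data.frame(
    method = c("PC", "PC", "PC", "GPDC", "GPDC"),
    condition = "resting",
    statistic = c(0.8, -0.4, 0.1, 0.5, 0.25))
  out <- normalize_statistics(df)
  expect_equal(max(abs(out$normalized[out$method == "PC"])), 1)
  expect_equal(out$normalized[2], -0.5)
  expect_equal(out$normalized[out$method == "GPDC"], c(1, 0.5))
  # scale invariance
  df2 <- df
  df2$statistic[df2$method == "PC"] <- df$statistic[df$method == "PC"] * 37
  expect_equal(normalize_statistics(df2)$normalized, out$normalized)
  # all statistics equal -> all map to 1
  df3 <- data.frame(method = "PC", condition = "m", statistic = c(2, 2))
  expect_equal(normalize_statistics(df3)$normalized, c(1, 1))
  # all-zero group warns and emits zeros
  df4 <- data.frame(method = "PC", condition = "m", statistic = c(0, 0))
  expect_warning(out4 <- normalize_statistics(df4), "zero")
  expect_equal(out4$normalized, c(0, 0))
})

test_that("the binomial detection-frequency screen flags repeated detections", {
  graphs <- list(
    resting = list(
      PC = make_graph(link_df(list("M1", "Put", 0)), "PC", "resting", regions4),
      GPDC = make_graph(link_df(list("M1", "Put", 0)), "GPDC", "resting", regions4),
      CMIknn = make_graph(link_df(list("M1", "Put", 0),
                                  list("SN", "Tal", 1)),
                          "CMIknn", "resting", regions4)),
    motor = list(
      PC = make_graph(link_df(list("M1", "Put", 0)), "PC", "motor", regions4),
      GPDC = make_graph(link_df(list("M1", "Put", 0)), "GPDC", "motor", regions4),
      CMIknn = make_graph(empty_links(), "CMIknn", "motor", regions4)))
  scr <- binomial_screen(classify_links(graphs), alpha = 0.01)
  row_mp <- scr[scr$source == "M1" & scr$target == "Put", ]
  row_st <- scr[scr$source == "SN" & scr$target == "Tal", ]
  expect_equal(row_mp$detections, 5L)
  expect_true(row_mp$pass)   # 5 of 6 cells at alpha = 0.01 is far from random
  expect_equal(row_st$detections, 1L)
  expect_false(row_st$pass)  # a single detection is compatible with chance
})

test_that("a causal graph renders as a node-link diagram", {
  g <- make_graph(link_df(list("M1", "Put", 0), list("Put", "SN", 1),
                          list("SN", "Tal", 2)), "PC", "resting", regions4)
  f <- tempfile(fileext = ".png")
  png(f)
  expect_no_error(plot(g))
  dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("classified output flows into long tables and mirrored wide matrices", {
  graphs <- list(
    resting = list(
      PC = make_graph(link_df(list("M1", "Put", 0, 0.8, 0.005),
                              list("Put", "SN", 1, -0.4, 0.005)),
                      "PC", "resting", regions4)),
    motor = list(
      PC = make_graph(link_df(list("M1", "Put", 0, 0.6, 0.005)),
                      "PC", "motor", regions4)))
  cls <- classify_links(graphs)
  expect_s3_class(cls, "classified_links")
  st <- statistic_table(cls)
  expect_true(all(abs(st$normalized) <= 1))
  # negative statistics keep their sign after scaling
  expect_lt(st$normalized[st$lag == 1 & st$condition == "resting"], 0)
  m0 <- link_matrix(st, "PC", 0, "resting", regions4)
  expect_equal(m0["Put", "M1"], m0["M1", "Put"])  # lag 0 is undirected
  expect_equal(m0["M1", "Put"], 1)
  pers <- cls$by_condition$resting$persistence
  expect_equal(sort(pers), c("permanent", "resting-only"))
})
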