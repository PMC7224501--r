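test_that("edge lists are parsed, normalised and dropped rows are counted", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "from,to,fromc,toc,dmonth,type,weight,transp,intl",
    "A,B,C01,C02,2013-05,Cattle,12.5,Truck,true",
    "B,,C01,C01,2013-06,goat,3,on foot,false",
    "C,D,C02,C02,2014-01,SHEEP,7,train,false",
    "D,E,C02,C02,not-a-month,sheep,7,train,false"
  ), path)
  tab <- read_edge_list(path)
  expect_s3_class(tab, "movement_table")
  expect_equal(nrow(tab), 2L)
  cnt <- provenance(tab)
  expect_equal(unname(cnt["entries_read"]), 4L)
  expect_equal(unname(cnt["dropped_incomplete"]), 1L)
  expect_equal(unname(cnt["dropped_unparseable"]), 1L)
  # category normalisation and recomputed international flag
  expect_equal(tab$type, c("cattle", "sheep"))
  expect_equal(tab$transp, c("vehicle", "train"))
  expect_equal(tab$intl, c(TRUE, FALSE))
  expect_equal(tab$year, c(2013L, 2014L))
})

test_that("an empty edge list yields an empty table with zero counters", {
  path <- tempfile(fileext = ".csv")
  writeLines("from,to,fromc,toc,dmonth,type,weight,transp,intl", path)
  tab <- read_edge_list(path)
  expect_equal(nrow(tab), 0L)
  expect_true(all(provenance(tab) == 0L))
})

test_that("unresolvable column mappings raise a configuration error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_edge_list(path), "column mapping")
})

test_that("a conflicting international flag is overridden with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "from,to,fromc,toc,dmonth,type,weight,transp,intl",
    "A,B,C01,C02,2013-05,cattle,1,vehicle,false"
  ), path)
  expect_warning(tab <- read_edge_list(path), "recomputed")
  expect_true(tab$intl)
})

test_that("node lists reject bad coordinates and duplicate codes", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,country,lat,lon",
    "A,Alpha,C01,0,0",
    "B,Beta,C01,95,1",
    "C,Gamma,C02,10.5,-3.2"
  ), path)
  nodes <- read_node_list(path)
  expect_equal(nodes$code, c("A", "C"))       # (0,0) legal, lat 95 rejected
  expect_equal(attr(nodes, "rejected"), "B")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,name,country,lat,lon", "A,x,C01,1,1", "A,y,C01,2,2"), dup)
  expect_error(read_node_list(dup), "duplicate market code.*A")
})

test_that("survey entries split into at most two legs and never self-loop", {
  nodes <- make_nodes(c("A", "S", "B"), lat = c(10, 11, 12), lon = 0:2)
  entry <- function(o, s, d) {
    data.frame(origin = o, survey = s, destination = d, dmonth = "2015-02",
               type = "cattle", heads = 5, transp = "vehicle",
               stringsAsFactors = FALSE)
  }
  # all three distinct: two legs
  tab <- split_survey_entries(entry("A", "S", "B"), nodes)
  expect_equal(nrow(tab), 2L)
  expect_setequal(paste(tab$from, tab$to), c("A S", "S B"))
  # origin equals survey point: only the outbound leg
  tab <- split_survey_entries(entry("S", "S", "B"), nodes)
  expect_equal(nrow(tab), 1L)
  expect_equal(paste(tab$from, tab$to), "S B")
  # A -> S -> A: both legs survive, neither is a self-loop
  tab <- split_survey_entries(entry("A", "S", "A"), nodes)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$from != tab$to))
  tab2 <- filter_movements(tab, nodes$code)
  expect_equal(nrow(tab2), 2L)
  # missing origin: only the outbound leg, counted
  tab <- split_survey_entries(entry(NA, "S", "B"), nodes)
  expect_equal(nrow(tab), 1L)
  expect_equal(unname(provenance(tab)["legs_missing_endpoint"]), 1L)
  # missing survey point is an error
  expect_error(split_survey_entries(entry("A", NA, "B"), nodes),
               "survey market")
})

test_that("filtering drops self-loops and unmapped records with counters", {
  tab <- make_table(from = c("A", "B", "B", "C"), to = c("B", "B", "Z", "A"))
  out <- filter_movements(tab, geolocatable = c("A", "B", "C"))
  expect_equal(nrow(out), 2L)
  cnt <- provenance(out)
  expect_equal(unname(cnt["dropped_self_loop"]), 1L)
  expect_equal(unname(cnt["dropped_unmapped"]), 1L)
})

test_that("records read are conserved across reading and filtering", {
  set.seed(4)
  codes <- c("A", "B", "C", "D", NA)
  for (i in 1:5) {
    n <- 40
    tab <- make_table(from = sample(codes, n, TRUE),
                      to = sample(codes, n, TRUE))
    out <- filter_movements(tab, geolocatable = c("A", "B", "C"))
    cnt <- provenance(out)
    base <- if (cnt["records_split"] > 0) cnt["records_split"] else
      cnt["entries_read"]
    drops <- sum(cnt[c("dropped_incomplete", "dropped_unparseable",
                       "dropped_bad_category", "dropped_unmapped",
                       "dropped_self_loop")])
    expect_equal(nrow(out), unname(base - drops))
  }
})

test_that("summaries count every record and percentages sum to 100", {
  tab <- make_table(from = c("A", "A", "B", "C"), to = c("B", "C", "C", "A"),
                    fromc = c("C01", "C01", "C02", "C02"),
                    toc = c("C02", "C01", "C02", "C01"))
  for (dim in c("movement-type", "livestock", "transport",
                "origin-country", "destination-country")) {
    s <- summarize_movements(tab, dim)
    expect_equal(sum(s$n), nrow(tab))
    expect_equal(sum(s$pct), 100, tolerance = 1e-9)
  }
  s <- summarize_movements(tab, "movement-type")
  expect_equal(s$n[s$category == "international"], 2L)
  # single-record table: one category at 100%
  one <- make_table("A", "B")
  s1 <- summarize_movements(one, "livestock")
  expect_equal(s1$pct, 100)
  # empty table: explicit empty summary, no division by zero
  empty <- filter_movements(make_table("A", "A"), "A")
  expect_equal(nrow(summarize_movements(empty, "livestock")), 0L)
})

test_that("month-by-livestock summary is a complete monthly series", {
  tab <- make_table(from = c("A", "A", "B"), to = c("B", "C", "C"),
                    month = c("2015-01", "2015-02", "2015-01"))
  s <- summarize_movements(tab, "month-livestock")
  expect_equal(sum(s$n), 3L)
  expect_setequal(unique(s$month), c("2015-01", "2015-02"))
})

test_that("the canonical CSV round trip preserves every field", {
  tab <- make_table(from = c("A", "B"), to = c("B", "C"),
                    fromc = c("C01", "C02"), toc = c("C02", "C02"),
                    month = c("2013-01", "2016-12"), heads = c(1.25, 300))
  path <- tempfile(fileext = ".csv")
  write_movement_table(tab, path)
  back <- read_edge_list(path)
  for (col in c("from", "to", "fromc", "toc", "month", "type", "heads",
                "transp", "intl")) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
})
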