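test_that("parse_stalk_id splits the LocationYear_Plot-Stalk syntax", {
  id <- parse_stalk_id("ID2021_101-3")
  expect_equal(id$location, "ID")
  expect_equal(id$year, 2021L)
  expect_equal(id$plot, 101L)
  expect_equal(id$stalk, 3L)
  expect_equal(id$raw_text, "ID2021_101-3")

  id2 <- parse_stalk_id("Moscow2019_7-12")
  expect_equal(id2$location, "Moscow")
  expect_equal(id2$year, 2019L)
  expect_equal(id2$stalk, 12L)
})

test_that("identifiers round-trip through parsing", {
  for (txt in c("ID2021_101-3", "KY2022_1-1", "SC2020_9999-42")) {
    expect_identical(parse_stalk_id(txt)$raw_text, txt)
    expect_identical(as.character(parse_stalk_id(txt)), txt)
  }
})

test_that("prohibited filename characters and malformed syntax are rejected", {
  expect_error(parse_stalk_id("ID2021_101.3"), "prohibited.*'\\.'")
  expect_error(parse_stalk_id("ID2021_101/3"), "prohibited")
  expect_error(parse_stalk_id("ID2021_1*1-3"), "prohibited")
  expect_error(parse_stalk_id(""), "empty")
  expect_error(parse_stalk_id("2021_101-3"), "location")
  expect_error(parse_stalk_id("ID21_101-3"), "4-digit year")
  expect_error(parse_stalk_id("ID2021-101-3"), "_")
  expect_error(parse_stalk_id("ID2021_1013"), "-")
})

test_that("clean triple payloads come back unchanged with an empty report", {
  for (id in c("ID2021_101-3", "AB1_1-1", "KY2022_55-4")) {
    res <- correct_scanned_payload(triple_payload(id), parse = FALSE)
    expect_identical(res$id_text, id)
    expect_identical(nrow(res$corrections), 0L)
  }
})

test_that("a single misread character is corrected and reported", {
  res <- correct_scanned_payload("AB1_1-1__AX1_1-1__AB1_1-1", parse = FALSE)
  expect_identical(res$id_text, "AB1_1-1")
  expect_identical(nrow(res$corrections), 1L)
  expect_identical(res$corrections$position, 2L)
  expect_identical(res$corrections$copy, 2L)
  expect_identical(res$corrections$observed, "X")
  expect_identical(res$corrections$corrected, "B")
})

test_that("every single-character corruption of one copy is recovered", {
  ids <- c("ID2021_101-3", "KY2022_5-1")
  alphabet <- c(LETTERS[1:6], as.character(0:9))
  for (id in ids) {
    chars <- strsplit(id, "")[[1]]
    for (pos in seq_along(chars)) {
      for (copy in 1:3) {
        for (sub in setdiff(alphabet, chars[[pos]])) {
          copies <- rep(id, 3)
          bad <- chars
          bad[[pos]] <- sub
          copies[[copy]] <- paste(bad, collapse = "")
          res <- correct_scanned_payload(paste(copies, collapse = "__"),
                                         parse = FALSE)
          expect_identical(res$id_text, id)
          expect_identical(nrow(res$corrections), 1L)
        }
      }
    }
  }
})

test_that("unalignable or three-way-disagreeing payloads are fatal", {
  expect_error(correct_scanned_payload("AB__AX__AY"), "disagree at position 2")
  expect_error(correct_scanned_payload("AB__AB__A"), "unequal lengths")
  expect_error(correct_scanned_payload("AB__AB"), "expected 3 copies")
})

test_that("the copy delimiter is configurable", {
  res <- correct_scanned_payload("AB1_1-1;;AB1_1-1;;AX1_1-1",
                                 delimiter = ";;", parse = FALSE)
  expect_identical(res$id_text, "AB1_1-1")
  expect_identical(res$corrections$copy, 3L)
})
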