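test_that("binarization recodes 1/2 as present and is idempotent", {
  raw <- matrix(c(0, 1, 2, 0,
                  2, 0, 1, 1,
                  0, 0, 0, 2), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  sm <- binarize_items(raw)
  expect_identical(unname(sm$values[1, ]), c(0L, 1L, 1L, 0L))
  expect_identical(unname(sm$values[2, ]), c(1L, 0L, 1L, 1L))
  expect_true(all(sm$values %in% 0:1))
  # idempotent on already-binary input
  sm2 <- binarize_items(sm$values)
  expect_identical(sm2$values, sm$values)
})

test_that("binarization flags zero-variance items and rejects bad ratings", {
  raw <- cbind(a = c(0, 0, 0), b = c(1, 2, 1), c = c(2, 0, 1))
  expect_warning(sm <- binarize_items(raw), "zero-variance.*a")
  expect_identical(unname(sm$values[, "a"]), c(0L, 0L, 0L))
  bad <- raw; bad[2, 3] <- 3
  expect_error(binarize_items(bad), "row 2, column 'c'")
})

test_that("symptom_matrix validates shape, labels and cells", {
  v <- cbind(a = c(0, 1), b = c(1, 0))
  sm <- symptom_matrix(v, domain_tags = c("depression", "anxiety"),
                       wave_label = "5")
  expect_s3_class(sm, "symptom_matrix")
  expect_error(symptom_matrix(v[, 1, drop = FALSE]), "2 items")
  expect_error(symptom_matrix(cbind(a = c(0, 2), b = c(1, 0))), "0 or 1")
  expect_error(symptom_matrix(v, node_labels = c("a", "a")), "unique")
  expect_error(symptom_matrix(cbind(a = c(0, NA), b = c(1, 0))), "issing")
  expect_error(symptom_matrix(v, domain_tags = c("depression", "mood")),
               "unknown domain")
})

test_that("load_panel round-trips CSV waves and drops incomplete rows", {
  dir <- withr::local_tempdir()
  items <- c("cry", "worry", "sad")
  meta <- data.frame(item = items, domain = c("depression", "anxiety", "depression"))
  set.seed(1)
  mk <- function(n) {
    d <- as.data.frame(matrix(rbinom(n * 3, 1, 0.4), n, 3,
                              dimnames = list(NULL, items)))
    cbind(subject_id = paste0("s", seq_len(n)), d)
  }
  w1 <- mk(30); w2 <- mk(30)
  w2$worry[4] <- NA  # incomplete case
  write.csv(w1, file.path(dir, "w1.csv"), row.names = FALSE)
  write.csv(w2, file.path(dir, "w2.csv"), row.names = FALSE)
  paths <- c(age5 = file.path(dir, "w1.csv"), age6 = file.path(dir, "w2.csv"))
  expect_message(panel <- load_panel(paths, meta), "dropped 1 incomplete")
  expect_s3_class(panel, "wave_panel")
  expect_identical(names(panel$waves), c("age5", "age6"))
  expect_identical(panel$waves[[1]]$node_labels, items)
  expect_identical(attr(panel, "drop_log"), c(age5 = 0L, age6 = 1L))
  expect_equal(nrow(panel$waves[[2]]$values), 29)
  expect_identical(panel$waves[[1]]$domain_tags, meta$domain)
  # missing item column is a hard error naming the item
  w3 <- w1[, -2]
  write.csv(w3, file.path(dir, "w3.csv"), row.names = FALSE)
  expect_error(load_panel(c(a = file.path(dir, "w3.csv")), meta), "cry")
})

test_that("load -> write -> load is the identity on the data model", {
  dir <- withr::local_tempdir()
  set.seed(9)
  mk <- function(lb) symptom_matrix(
    matrix(rbinom(60, 1, 0.35), 20, 3,
           dimnames = list(NULL, c("cry", "worry", "sad"))),
    domain_tags = c("depression", "anxiety", "depression"),
    subject_ids = paste0("s", 1:20), wave_label = lb)
  panel <- wave_panel(list(mk("5"), mk("6")))
  paths <- write_panel(panel, dir)
  back <- load_panel(paths, file.path(dir, "node_meta.csv"))
  for (w in 1:2) {
    expect_identical(back$waves[[w]]$values, panel$waves[[w]]$values)
    expect_identical(back$waves[[w]]$domain_tags, panel$waves[[w]]$domain_tags)
    expect_identical(back$waves[[w]]$subject_ids, panel$waves[[w]]$subject_ids)
  }
  expect_identical(names(back$waves), names(panel$waves))
})

test_that("wave_panel enforces shared node sets and detects alignment", {
  v <- cbind(a = c(0, 1, 1), b = c(1, 0, 1))
  m1 <- symptom_matrix(v, subject_ids = c("s1", "s2", "s3"), wave_label = "5")
  m2 <- symptom_matrix(v[c(2, 1, 3), ], subject_ids = c("s2", "s1", "s3"),
                       wave_label = "6")
  panel <- wave_panel(list(m1, m2))
  expect_identical(panel$alignment, c("s1", "s2", "s3"))
  m3 <- symptom_matrix(v, subject_ids = c("t1", "t2", "t3"), wave_label = "7")
  expect_null(wave_panel(list(m1, m3))$alignment)
  m4 <- symptom_matrix(v[, 2:1], wave_label = "8")
  expect_error(wave_panel(list(m1, m4)), "identical node labels")
  expect_error(wave_panel(list(m1, m1)), "unique")
})

test_that("network writers round-trip losslessly in both formats", {
  omega <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  omega[1, 2] <- omega[2, 1] <- 0.4
  net <- ising_params(rep(0, 3), omega)
  f <- withr::local_tempfile(fileext = ".csv")
  write_network(net, f, format = "edgelist")
  # exactly one edge row (zero-weight pairs omitted), plus node header + csv header
  expect_length(readLines(f), 3L)
  back <- read_network(f, format = "edgelist")
  expect_identical(back$node_labels, c("a", "b", "c"))
  expect_lt(max(abs(back$omega - omega)), 1e-9)

  omega2 <- random_graph(5, density = 0.6, seed = 3)
  omega2[1, 2] <- omega2[2, 1] <- 1 / 3  # non-terminating decimal
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_network(omega2, f2, format = "graphml")
  back2 <- read_network(f2, format = "graphml")
  expect_lt(max(abs(back2$omega[rownames(omega2), rownames(omega2)] - omega2)), 1e-9)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_network(omega2, f3)
  expect_lt(max(abs(read_network(f3)$omega - omega2)), 1e-9)

  asym <- omega; asym[1, 2] <- 0.5
  expect_error(write_network(asym, f), "symmetric")
})
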