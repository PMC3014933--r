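mk_events <- function(pairs) {
  if (!length(pairs))
    return(mk_events(list(c("x", "x")))[0, , drop = FALSE])
  data.frame(query_id = "q", inserted_id = seq_along(pairs) + 10L,
             host_id = 1L,
             inserted_type = vapply(pairs, `[`, character(1), 1L),
             host_type = vapply(pairs, `[`, character(1), 2L),
             inserted_begin = 1L, inserted_end = 2L, gap_begin = 0L,
             gap_end = 3L, consensus_overlap = 10L, strand = "+",
             self_insertion = vapply(pairs, function(p) p[1] == p[2], logical(1)),
             stringsAsFactors = FALSE)
}

mk_instances <- function(types) {
  data.frame(query_id = "q", element_id = seq_along(types), type = types,
             class = "SINE/Alu", strand = "+", n_fragments = 1L,
             query_begin = 1L, query_end = 2L, min_fragment_span = 300L,
             stringsAsFactors = FALSE)
}

test_that("events tally into directional counts with copy numbers", {
  ev <- mk_events(list(c("A", "B"), c("A", "B"), c("C", "B")))
  inst <- mk_instances(c("A", "A", "A", "B", "B", "C"))
  m <- build_tint_matrix(ev, inst)
  expect_identical(m$counts["A", "B"], 2L)
  expect_identical(m$counts["C", "B"], 1L)
  expect_identical(unname(tint_margins(m)$host_total["B"]), 3)
  expect_identical(sum(m$counts), 3L)
  expect_identical(unname(m$copy_number), c(3L, 2L, 1L))
})

test_that("zero events give an all-zero matrix with correct copy numbers", {
  inst <- mk_instances(c("A", "B", "B"))
  m <- build_tint_matrix(mk_events(list()), inst, types = c("A", "B"))
  expect_true(all(m$counts == 0L))
  expect_identical(unname(m$copy_number), c(1L, 2L))
})

test_that("self-insertions are excluded by default and kept on request", {
  ev <- mk_events(list(c("A", "A"), c("A", "B")))
  inst <- mk_instances(c("A", "B"))
  m0 <- build_tint_matrix(ev, inst)
  expect_identical(sum(m0$counts), 1L)
  expect_identical(unname(diag(m0$counts)), c(0L, 0L))
  m1 <- build_tint_matrix(ev, inst, include_self = TRUE)
  expect_identical(m1$counts["A", "A"], 1L)
  expect_identical(sum(m1$counts), 2L)
})

test_that("events referencing unknown subtypes are a consistency error", {
  ev <- mk_events(list(c("A", "Z")))
  expect_error(build_tint_matrix(ev, mk_instances(c("A", "B"))),
               "absent from instances", class = "tint_data_error")
})

test_that("merging related subtypes conserves totals and pools copy numbers", {
  ev <- mk_events(list(c("AluYRb", "AluYRc"), c("AluYRc", "AluYRd"),
                       c("AluYRb", "AluY"), c("AluY", "AluYRd"),
                       c("AluY", "AluSx"), c("AluSx", "AluYRb")))
  inst <- mk_instances(c("AluYRb", "AluYRc", "AluYRd", "AluY", "AluY", "AluSx"))
  m <- build_tint_matrix(ev, inst)
  merged <- merge_types(m, list(AluYR = c("AluYRb", "AluYRc", "AluYRd")))
  expect_setequal(merged$types, c("AluYR", "AluY", "AluSx"))
  expect_identical(sum(merged$counts), sum(m$counts))
  expect_identical(sum(merged$copy_number), sum(m$copy_number))
  # within-group cross counts land on the merged diagonal
  expect_identical(merged$counts["AluYR", "AluYR"], 2L)
  expect_identical(merged$counts["AluYR", "AluY"], 1L)
})

test_that("singleton groups only rename", {
  ev <- mk_events(list(c("A", "B"), c("B", "A")))
  m <- build_tint_matrix(ev, mk_instances(c("A", "B")))
  r <- merge_types(m, list(A2 = "A"))
  expect_identical(r$types, c("A2", "B"))
  expect_identical(unname(r$counts), unname(m$counts))
  expect_identical(unname(r$copy_number), unname(m$copy_number))
})

test_that("overlapping or unknown merge groups are rejected", {
  m <- build_tint_matrix(mk_events(list(c("A", "B"))), mk_instances(c("A", "B")))
  expect_error(merge_types(m, list(G1 = c("A", "B"), G2 = "B")),
               "overlap", class = "tint_config_error")
  expect_error(merge_types(m, list(G1 = c("A", "nope"))),
               "unknown", class = "tint_config_error")
})

test_that("interaction filtering removes weakly connected subtypes to a fixed point", {
  # D interacts only with C; C interacts with A, B and D. Removing D leaves C
  # with two partners, so the cascade stops there.
  ev <- mk_events(list(c("A", "B"), c("B", "A"), c("A", "C"), c("C", "B"),
                       c("D", "C")))
  m <- build_tint_matrix(ev, mk_instances(c("A", "B", "C", "D")))
  f <- filter_types(m)
  expect_setequal(f$types, c("A", "B", "C"))
  expect_identical(attr(f, "removed"), "D")
  # removing a type can strand another's last partner: dropping D leaves E
  # with a single partner, so E falls in the next iteration
  ev2 <- mk_events(list(c("A", "B"), c("B", "C"), c("C", "A"),
                        c("D", "E"), c("E", "A")))
  m2 <- build_tint_matrix(ev2, mk_instances(c("A", "B", "C", "D", "E")))
  f2 <- filter_types(m2)
  expect_setequal(f2$types, c("A", "B", "C"))
  expect_identical(attr(f2, "removed"), c("D", "E"))
  # idempotent at the fixed point
  f3 <- filter_types(f2)
  expect_identical(f3$types, f2$types)
  expect_identical(f3$counts, f2$counts)
})

test_that("filtering everything away is an error advising relaxed conditions", {
  m <- build_tint_matrix(mk_events(list(c("A", "B"))), mk_instances(c("A", "B")))
  expect_error(filter_types(m), "relaxed", class = "tint_data_error")
})

test_that("matrix serialization round-trips and states its orientation", {
  sim <- simulate_tints(small_sim_config(seed = 5))
  ev <- detect_tints(sim$hits)
  m <- build_tint_matrix(ev, group_elements(sim$hits))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tint_matrix(m, f)
  expect_match(readLines(f)[2], "rows=inserted cols=host")
  back <- read_tint_matrix(f)
  expect_identical(back$types, m$types)
  expect_identical(back$counts, m$counts)
  expect_identical(back$copy_number, m$copy_number)
})

test_that("grouping files parse into named member lists", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "AluYR = AluYRb, AluYRc , AluYRd", "",
               "AluJ=AluJo,AluJb"), f)
  g <- read_groups(f)
  expect_identical(g$AluYR, c("AluYRb", "AluYRc", "AluYRd"))
  expect_identical(g$AluJ, c("AluJo", "AluJb"))
  writeLines("badline", f)
  expect_error(read_groups(f), class = "tint_config_error")
})

test_that("rendered matrix table carries correct margins", {
  ev <- mk_events(list(c("A", "B"), c("A", "B"), c("B", "A")))
  m <- build_tint_matrix(ev, mk_instances(c("A", "B")))
  tab <- render_matrix_table(m)
  expect_identical(unname(tab[nrow(tab), 1]), "host_total")
  expect_identical(unname(tab[1, "inserted_total"]), "2")
  expect_identical(unname(tab[nrow(tab), "A"]), "1")
  expect_identical(unname(tab[nrow(tab), "B"]), "2")
  # zero matrix renders all-zero margins
  z <- build_tint_matrix(ev[0, ], mk_instances(c("A", "B")), types = c("A", "B"))
  zt <- render_matrix_table(z)
  expect_true(all(zt[nrow(zt), c("A", "B", "inserted_total")] == "0"))
})
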