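test_that("symbol standardization maps, conserves, and dedups", {
  edges <- data.frame(
    component_id = c("C1", "C1", "C1", "C2"),
    raw_name = c("tumor necrosis factor", "TNF alpha", "mystery protein",
                 "interleukin 6"),
    stringsAsFactors = FALSE)
  mapping <- data.frame(
    raw_name = c("tumor necrosis factor", "TNF alpha", "interleukin 6"),
    symbol = c("TNF", "tnf", "IL6"), stringsAsFactors = FALSE)
  res <- standardize_symbols(edges, mapping)
  # two raw names resolving to TNF for C1 collapse to one edge
  expect_equal(nrow(res$mapped), 2)
  expect_setequal(res$mapped$symbol, c("TNF", "IL6"))
  expect_equal(res$unmapped$raw_name, "mystery protein")
  expect_equal(res$total_mapped + nrow(res$unmapped), res$total_raw)
})

test_that("conflicting raw-name mappings are an error naming the conflict", {
  edges <- data.frame(component_id = "C1", raw_name = "p", stringsAsFactors = FALSE)
  mapping <- data.frame(raw_name = c("p", "p"), symbol = c("TNF", "IL6"),
                        stringsAsFactors = FALSE)
  expect_error(standardize_symbols(edges, mapping), "conflicting.*p")
  expect_error(standardize_symbols(edges, mapping[0, ]), "empty")
})

test_that("standardization conserves records on random fixtures", {
  set.seed(11)
  symbols <- sprintf("G%03d", 1:50)
  mapping <- data.frame(raw_name = paste0("raw_", symbols), symbol = symbols,
                        stringsAsFactors = FALSE)
  for (rep in 1:20) {
    edges <- data.frame(
      component_id = sample(sprintf("C%02d", 1:10), 80, replace = TRUE),
      raw_name = sample(c(mapping$raw_name, "unknown_1", "unknown_2"),
                        80, replace = TRUE),
      stringsAsFactors = FALSE)
    res <- standardize_symbols(edges, mapping)
    expect_equal(res$total_mapped + nrow(res$unmapped), nrow(edges))
    expect_true(all(res$mapped$symbol %in% symbols))
  }
})

test_that("assembly attributes records per herb and dedups the union", {
  sizes <- c(SZR = 80, GS = 90, YHS = 1493, XHC = 232, JL = 143, ML = 33)
  comps <- data.frame(component_id = paste0("C", seq_along(sizes)),
                      name = names(sizes), herbs = names(sizes),
                      ob = 40, dl = 0.3, rescued = FALSE, source = "",
                      stringsAsFactors = FALSE)
  mapped <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    data.frame(component_id = paste0("C", i),
               symbol = sprintf("H%d_G%04d", i, seq_len(sizes[i])),
               stringsAsFactors = FALSE)
  }))
  rep <- assemble_targets(mapped, comps)
  expect_equal(rep$total_mapped, 2071)
  expect_equal(as.vector(rep$per_herb_counts[names(sizes)]),
               as.vector(sizes), ignore_attr = TRUE)
  expect_equal(sum(rep$per_herb_counts), rep$total_mapped)
})

test_that("assembly handles duplicates, multi-herb components, empty input", {
  comps <- data.frame(component_id = c("C1", "C2"), name = c("a", "b"),
                      herbs = c("SZR;GS", "GS"), ob = 40, dl = 0.3,
                      rescued = FALSE, source = "", stringsAsFactors = FALSE)
  mapped <- data.frame(component_id = c("C1", "C1", "C2"),
                       symbol = c("A", "B", "A"), stringsAsFactors = FALSE)
  rep <- assemble_targets(mapped, comps)
  expect_setequal(rep$union_targets, c("A", "B"))
  # C1's records count once for each of its two herbs
  expect_equal(as.vector(rep$per_herb_counts["SZR"]), 2, ignore_attr = TRUE)
  expect_equal(as.vector(rep$per_herb_counts["GS"]), 3, ignore_attr = TRUE)

  empty <- assemble_targets(mapped[0, ], comps)
  expect_equal(empty$total_mapped, 0)
  expect_length(empty$union_targets, 0)

  bad <- data.frame(component_id = "C9", symbol = "A", stringsAsFactors = FALSE)
  expect_error(assemble_targets(bad, comps), "unknown component")
})

test_that("disease intersection counts match brute-force enumeration", {
  res <- intersect_disease(c("A", "B", "C"), af = c("B", "C", "D"),
                           osahs = c("C", "D", "E"),
                           combined = c("B", "C", "D", "E"))
  # brute-force membership tally over the five symbols
  uni <- c("A", "B", "C"); af <- c("B", "C", "D"); os <- c("C", "D", "E")
  expect_equal(res$herb_af, sum(vapply(uni, function(g) g %in% af, logical(1))))
  expect_equal(res$herb_osahs, sum(vapply(uni, function(g) g %in% os, logical(1))))
  expect_equal(res$herb_both,
               sum(vapply(uni, function(g) (g %in% af) && (g %in% os), logical(1))))
  expect_equal(res$herb_af, 2)
  expect_equal(res$herb_osahs, 1)
  expect_equal(res$herb_both, 1)
  expect_setequal(res$putative_targets, c("B", "C"))
})

test_that("degenerate disease sets abort with a clear message", {
  expect_error(intersect_disease(c("A"), c("A"), c("A"), character()),
               "empty")
  expect_error(intersect_disease(c("A", "B"), c("C"), c("D"), c("E", "F")),
               "no herb target intersects")
  # identity: combined == union
  res <- intersect_disease(c("A", "B"), c("X"), c("Y"), c("A", "B"))
  expect_setequal(res$putative_targets, c("A", "B"))
})

test_that("intersection results are order- and size-bounded", {
  set.seed(3)
  pool <- sprintf("G%03d", 1:60)
  for (rep in 1:25) {
    uni <- sample(pool, 25); af <- sample(pool, 20); os <- sample(pool, 20)
    comb <- unique(c(sample(uni, 5), sample(pool, 15)))  # nonempty putative
    r1 <- intersect_disease(uni, af, os, comb)
    r2 <- intersect_disease(sample(uni), sample(af), sample(os), sample(comb))
    expect_equal(r1[c("herb_af", "herb_osahs", "herb_both")],
                 r2[c("herb_af", "herb_osahs", "herb_both")])
    expect_identical(r1$putative_targets, r2$putative_targets)
    expect_lte(length(r1$putative_targets), min(length(uni), length(comb)))
  }
})
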