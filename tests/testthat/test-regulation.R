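test_that("detectability requires a strictly positive count in some sample", {
  expr <- data.frame(s1 = c(5, 0, 1), s2 = c(0, 0, 0), row.names = c("A", "B", "C"))
  expect_equal(detectable_genes(expr, c("A", "B", "C")), c("A", "C"))
  zero <- data.frame(s1 = c(0, 0), row.names = c("A", "B"))
  expect_equal(detectable_genes(zero, c("A", "B")), character(0))
  expect_message(d <- detectable_genes(expr, c("A", "ZZ")), "absent")
  expect_equal(d, "A")
  expect_error(detectable_genes(expr, character(0)), "empty")
})

test_that("log2 fold change is pseudocounted and antisymmetric", {
  expect_equal(log2_fold_change(16, 4, 0), 2.0)
  expect_equal(log2_fold_change(8, 0, 1), log2(9))
  expect_equal(log2_fold_change(7, 7, 2), 0.0)
  expect_error(log2_fold_change(0, 0, 0), "undefined")
  expect_error(log2_fold_change(-1, 2, 1), "non-negative")
  withr::with_seed(2, {
    a <- runif(50, 0, 100); b <- runif(50, 0, 100)
    expect_equal(log2_fold_change(a, b, 1), -log2_fold_change(b, a, 1))
  })
})

test_that("direction calls are inclusive at the +/- threshold and mirror-symmetric", {
  cfg <- regulation_config()
  expect_equal(call_direction(0.5, cfg), "Up")
  expect_equal(call_direction(-0.2, cfg), "None")
  expect_equal(call_direction(0.4, cfg), "Up")
  expect_equal(call_direction(-0.4, cfg), "Down")
  expect_error(call_direction(NaN, cfg), "finite")
  withr::with_seed(8, {
    x <- runif(200, -2, 2)
    mirror <- c(Up = "Down", Down = "Up", None = "None")
    expect_identical(call_direction(-x, cfg), unname(mirror[call_direction(x, cfg)]))
  })
})

test_that("consensus needs the same direction in at least two datasets", {
  cc <- function(calls) consensus_call(
    data.frame(dataset_id = sprintf("d%d", seq_along(calls)), call = calls))
  expect_equal(cc(c("Up", "Up", "Up"))$consensus, "Up")
  expect_equal(cc(c("Down", "Down", "-"))$consensus, "Down")
  r <- cc(c("Up", "Down", "-"))
  expect_equal(r$consensus, "None")
  expect_true(r$conflict)
  expect_equal(cc(c("Up", "-", "-"))$consensus, "None")
  expect_false(cc(c("Up", "Up", "-"))$conflict)
  expect_error(consensus_call(data.frame(dataset_id = c("d1", "d1"),
                                         call = c("Up", "Up"))), "duplicate")
})

test_that("patient-versus-sibling calls flag a planted deficit in both states", {
  pat <- data.frame(monocyte = c(2, 10), macrophage = c(2.5, 9),
                    row.names = c("SEMA7A", "OTHER"))
  sib <- data.frame(monocyte = c(5, 10), macrophage = c(6, 11),
                    row.names = c("SEMA7A", "OTHER"))
  cfg <- regulation_config(pseudocount = 0)
  out <- patient_comparison(pat, sib, c("SEMA7A", "OTHER"), cfg)
  sema <- out[out$gene == "SEMA7A", ]
  expect_equal(sema$call, c("Down", "Down"))
  expect_equal(sema$log2fc[sema$condition == "monocyte"], log2(2 / 5))
  other <- out[out$gene == "OTHER", ]
  expect_true(all(other$call == "None"))
  expect_message(patient_comparison(pat, sib, c("SEMA7A", "MISSING"), cfg), "skipped")
})

test_that("correlation returns Pearson r with a two-sided p-value", {
  expect_equal(qki_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(qki_correlation(c(1, 2, 3), c(6, 4, 2))$r, -1.0)
  expect_error(qki_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(qki_correlation(c(1, 2), c(1, 2)), ">= 3")
  withr::with_seed(19, {
    x <- runif(50); y <- x + rnorm(50, 0, 0.1)
    r <- qki_correlation(x, y)
    expect_gt(r$r, 0.9)
    expect_lt(r$p, 1e-6)
    ct <- stats::cor.test(x, y)
    expect_equal(r$r, unname(ct$estimate))
    expect_equal(r$p, ct$p.value)
  })
})

test_that("count/fold-change join is an inner join in gene order", {
  out <- join_counts_fc(c(G1 = 2L), data.frame(gene = "G1", log2fc = 1.0))
  expect_equal(out, data.frame(gene = "G1", qre_count = 2L, log2fc = 1.0))
  disjoint <- join_counts_fc(c(G1 = 2L), data.frame(gene = "G2", log2fc = 1.0))
  expect_equal(nrow(disjoint), 0L)
  withr::with_seed(4, {
    genes <- sprintf("G%02d", 1:10)
    counts <- stats::setNames(sample.int(5L, 10L, replace = TRUE), sample(genes))
    fc <- data.frame(gene = sample(genes, 7), log2fc = rnorm(7))
    out <- join_counts_fc(counts, fc)
    expect_equal(nrow(out), 7L)
    expect_equal(out$gene, sort(fc$gene))
  })
})

test_that("packaged call matrix is complete and internally consistent", {
  tb <- load_ngc_call_matrix()
  expect_equal(length(unique(tb$gene)), 17L)
  expect_equal(nrow(tb), 51L)
  expect_true(all(tb$call %in% c("Up", "Down", "-")))
  expect_true(all(table(tb$gene) == 3L))
})
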