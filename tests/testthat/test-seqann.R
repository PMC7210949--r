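# Toy sequence with every motif at a hand-checked position:
# M A K R A A A A V G W P P V R S I R A A A A A V K V D D
# 1 2 3 4 5 6 7 8 9 ...            18            24    28
TOY <- "MAKRAAAAVGWPPVRSIRAAAAAVKVDD"

test_that("domain segmentation recovers the hand-derived spans on the toy", {
  ann <- segment_domains(protein_record("toy", TOY))
  expect_true(ann$canonical)
  expect_equal(ann$spans$DI, c(1L, 4L))
  expect_equal(ann$spans$linker, c(5L, 8L))
  expect_equal(ann$spans$degron, c(9L, 18L))
  expect_equal(ann$spans$degron_tail, c(19L, 23L))
  expect_equal(ann$spans$PB1, c(24L, 28L))
  expect_equal(ann$kr_position, 3L)
  expect_equal(degron_tail_length(ann), 5L)
})

test_that("degron variants match and absence yields non-canonical", {
  # Ile/Gly degron variant (the IAA12-style GWPPIG core)
  ann <- segment_domains(protein_record("ig", "AAKRAAVGWPPIGAARAAVKVAAA"))
  expect_true(ann$canonical)
  # no degron at all
  ann2 <- segment_domains(protein_record("nc", "AAKRAAAAAAAAVKVAAA"))
  expect_false(ann2$canonical)
  expect_null(ann2$spans$degron)
  # degron but no VKV: partial annotation, flagged
  ann3 <- segment_domains(protein_record("novkv", "AAKRAAVGWPPVRSIRAAAA"))
  expect_false(ann3$canonical)
  expect_match(paste(ann3$warnings, collapse = " "), "VKV")
  expect_error(degron_tail_length(ann3), "canonical")
})

test_that("no KR upstream leaves DI empty and linker from residue 1", {
  ann <- segment_domains(protein_record("nokr", "AAAAVGWPPVRSIRAAVKVAAA"))
  expect_true(ann$canonical)
  expect_null(ann$spans$DI)
  expect_equal(ann$spans$linker, c(1L, 4L))
})

test_that("multiple degron matches use the first and warn", {
  s <- paste0("AKR", "VGWPPVRAAR", "AA", "VGWPPVRAAR", "AAVKVAA")
  ann <- segment_domains(protein_record("two", s))
  expect_equal(ann$spans$degron[1], 4L)
  expect_match(paste(ann$warnings, collapse = " "), "degron matches")
})

test_that("canonical spans reassemble the sequence with no gaps or overlaps", {
  gen <- gen_sequences(11, n_canonical = 8, n_noncanonical = 0)
  for (id in names(gen$records)) {
    ann <- segment_domains(gen$records[[id]])
    expect_true(ann$canonical)
    sp <- do.call(rbind, ann$spans)
    sp <- sp[order(sp[, 1]), , drop = FALSE]
    dimnames(sp) <- NULL
    expect_equal(sp[1, 1], 1L)
    expect_equal(sp[nrow(sp), 2], ann$n_res)
    if (nrow(sp) > 1L)
      expect_equal(sp[-1, 1], sp[-nrow(sp), 2] + 1L)
  }
})

test_that("disorder classification respects the closed intermediate band", {
  r <- classify_disorder(c(0.7, 0.5, 0.3))
  expect_equal(as.character(r$category),
               c("disordered", "intermediate", "ordered"))
  expect_equal(unname(r$fractions), rep(1 / 3, 3))
  # boundary scores fall in the intermediate category on both sides
  expect_equal(as.character(classify_disorder(c(0.4, 0.6))$category),
               c("intermediate", "intermediate"))
  expect_equal(unname(classify_disorder(rep(0, 5))$fractions), c(1, 0, 0))
  expect_error(classify_disorder(numeric(0)), "empty")
})

test_that("disorder fractions sum to one for arbitrary profiles", {
  set.seed(42)
  for (i in 1:20) {
    sc <- runif(sample(3:200, 1))
    expect_equal(sum(classify_disorder(sc)$fractions), 1, tolerance = 1e-12)
  }
})

test_that("hydropathy profile matches single-residue values and reverses", {
  expect_equal(hydropathy_profile(strrep("I", 7), 5), rep(4.5, 7))
  expect_equal(hydropathy_profile(strrep("R", 7), 5), rep(-4.5, 7))
  expect_equal(hydropathy_profile("IR", 1), c(4.5, -4.5))
  expect_error(hydropathy_profile("IR", 2), "odd")
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(hydropathy_profile(rev_s, 9), rev(hydropathy_profile(s, 9)))
})

test_that("site mapping assigns modules inclusively and flags out-of-range", {
  ann <- segment_domains(protein_record("toy", TOY))
  m <- map_sites(c(2L, 25L), ann)
  expect_equal(unname(m$per_domain_counts[c("DI", "PB1")]), c(1L, 1L))
  # boundary positions land in their span (inclusive ends)
  expect_equal(map_sites(18L, ann)$assignment$module, "degron")
  expect_equal(map_sites(19L, ann)$assignment$module, "degron_tail")
  expect_equal(map_sites(99L, ann)$assignment$module, "out_of_range")
  m0 <- map_sites(integer(0), ann)
  expect_true(all(m0$per_domain_counts == 0L))
  expect_equal(lysine_positions(TOY), c(3L, 25L))
})

test_that("tail length is offset-invariant and zero when degron abuts VKV", {
  s <- "AAKRAAVGWPPVRSIRVKVAAAA"
  ann <- segment_domains(protein_record("abut", s))
  expect_equal(degron_tail_length(ann), 0L)
  ann_off <- segment_domains(protein_record("abut", s, offset = 5L))
  expect_equal(degron_tail_length(ann_off), 0L)
})

test_that("protein records validate their sequence alphabet", {
  expect_error(protein_record("bad", "ACDEFZ"), "non-standard")
  expect_error(protein_record("empty", ""), "non-empty")
  expect_true(attr(protein_record("x", "ACDX"), "has_x"))
  expect_error(protein_record("neg", "ACD", offset = -1), "offset")
})
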