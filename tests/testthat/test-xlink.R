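make_xl_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein1 = r[[1]], residue1 = as.integer(r[[2]]),
               protein2 = r[[3]], residue2 = as.integer(r[[4]]),
               replicate = r[[5]], score = 100, stringsAsFactors = FALSE)))
}

test_that("offset correction shifts construct numbering to canonical", {
  df <- make_xl_df(list("TIR1", 100, "IAA7", 10, "rep1"))
  tab <- load_xl_table(df, offsets = c(IAA7 = 5))
  expect_equal(tab$protein_a, "IAA7")  # canonical endpoint order
  expect_equal(tab$residue_a, 5L)      # 10 - 5
  expect_equal(tab$residue_b, 100L)    # TIR1 side untouched
  # zero offset is the identity
  tab0 <- load_xl_table(df)
  expect_equal(sort(c(tab0$residue_a, tab0$residue_b)), c(10L, 100L))
  # non-positive corrected indices are flagged, not dropped
  tab_bad <- load_xl_table(make_xl_df(list("TIR1", 100, "IAA7", 3, "rep1")),
                           offsets = c(IAA7 = 5))
  expect_false(all(tab_bad$valid))
  expect_error(load_xl_table(data.frame(protein1 = "x")), "missing columns")
})

test_that("duplicate identifications collapse to one link per replicate", {
  df <- make_xl_df(list("TIR1", 150, "IAA7", 40, "rep1"),
                   list("TIR1", 150, "IAA7", 40, "rep1"),
                   list("IAA7", 40, "TIR1", 150, "rep2"))  # swapped endpoints
  tab <- load_xl_table(df)
  expect_equal(nrow(tab), 2L)
  net <- xl_network(tab)
  expect_equal(nrow(net$links), 1L)
  expect_equal(net$links$n_support, 2L)
})

test_that("replicate filter keeps >= min_support and labels support classes", {
  df <- make_xl_df(list("TIR1", 150, "IAA7", 40, "rep1"),
                   list("TIR1", 150, "IAA7", 40, "rep2"),
                   list("TIR1", 200, "IAA7", 60, "rep1"),
                   list("TIR1", 490, "IAA7", 90, "rep1"),
                   list("TIR1", 490, "IAA7", 90, "rep2"),
                   list("TIR1", 490, "IAA7", 90, "rep3"))
  net <- xl_network(load_xl_table(df), replicates = paste0("rep", 1:3))
  filt <- replicate_filter(net, 2)
  expect_equal(nrow(filt$links), 2L)
  sc <- stats::setNames(filt$links$support_class, filt$links$residue_b)
  expect_equal(unname(sc["150"]), "dashed")  # 2/3
  expect_equal(unname(sc["490"]), "solid")   # 3/3
  expect_error(replicate_filter(net, 4), "exceeds")
})

test_that("replicate filter is idempotent and monotone in min_support", {
  g <- gen_xl_table(21)
  net <- xl_network(g$table)
  f2 <- replicate_filter(net, 2)
  expect_equal(replicate_filter(f2, 2)$links, f2$links)
  f3 <- replicate_filter(net, 3)
  key <- function(n) paste(n$links$protein_a, n$links$residue_a,
                           n$links$protein_b, n$links$residue_b)
  expect_true(all(key(f3) %in% key(f2)))
})

test_that("planted reproducible links are recovered exactly, decoys dropped", {
  for (seed in c(7, 19, 33)) {
    g <- gen_xl_table(seed)
    filt <- replicate_filter(xl_network(g$table), g$truth$min_support)
    kept <- paste(filt$links$protein_a, filt$links$residue_a,
                  filt$links$protein_b, filt$links$residue_b, sep = "|")
    expect_setequal(kept, g$truth$true_pairs)
  }
})

test_that("intra/inter partition is exhaustive and by protein identity", {
  df <- make_xl_df(list("TIR1", 10, "TIR1", 90, "rep1"),
                   list("TIR1", 150, "IAA7", 40, "rep1"))
  net <- classify_links(xl_network(load_xl_table(df)))
  expect_setequal(net$links$link_class, c("intra", "inter"))
  expect_equal(sum(table(net$links$link_class)), nrow(net$links))
  i <- which(net$links$link_class == "intra")
  expect_equal(net$links$protein_a[i], net$links$protein_b[i])
})

test_that("1D single-linkage clustering matches the hand-derived spans", {
  cl <- cluster_residues(c(150, 160, 200, 490, 500), max_gap = 50)
  expect_equal(cl$start, c(150, 490))
  expect_equal(cl$end, c(200, 500))
  expect_equal(cluster_residues(42, 30)$start, 42)
  expect_equal(nrow(cluster_residues(c(1, 100, 400), max_gap = 500)), 1L)
  # spans are disjoint and cover every input position
  set.seed(9)
  pos <- sample(1:600, 40)
  cl2 <- cluster_residues(pos, 25)
  expect_true(all(cl2$start[-1] > cl2$end[-nrow(cl2)] + 25))
  members <- as.integer(unlist(strsplit(cl2$members, ",")))
  expect_setequal(members, unique(pos))
})

test_that("crosslinks become restraints with violation reporting", {
  beads <- data.frame(chain = c("T", "T", "I"), residue = c(150, 490, 40),
                      x = c(0, 80, 25), y = 0, z = 0)
  struct <- coarse_structure(beads)
  df <- make_xl_df(list("TIR1", 150, "IAA7", 40, "rep1"),
                   list("TIR1", 490, "IAA7", 40, "rep1"),
                   list("TIR1", 150, "IAA7", 999, "rep1"))
  net <- classify_links(xl_network(load_xl_table(df)))
  out <- xl_to_restraints(net, struct, chain_map = c(TIR1 = "T", IAA7 = "I"),
                          max_ca_ca = 30)
  expect_equal(nrow(out$restraints), 2L)   # one endpoint unresolvable
  expect_equal(nrow(out$unresolved), 1L)
  sat <- stats::setNames(out$report$satisfied, out$report$resid_b)
  expect_true(sat[["150"]])    # 25 A apart, max 30
  expect_false(sat[["490"]])   # 55 A apart, violated
})

test_that("degron-tail restraint bounds follow the polymer scaling laws", {
  a <- list(chain = "T", resid = 1); b <- list(chain = "I", resid = 1)
  r36 <- tail_restraint(36, a, b)
  r49 <- tail_restraint(49, a, b)
  expect_lt(r36$lower, r36$upper)
  expect_lt(r49$lower, r49$upper)
  # a longer disordered tail reaches farther
  expect_gt(r49$upper, r36$upper)
  expect_equal(r36$source, "TAIL")
  # bounds are the scaled NF / IDP Stokes radii of the peptide
  bands <- fold_class_bands()
  expect_equal(r36$upper, 2 * theoretical_rs(36 * 110, "IDP", bands))
  expect_equal(r36$lower, 2 * theoretical_rs(36 * 110, "NF", bands))
  lens <- c(1, 5, 10, 20, 40, 60)
  ub <- vapply(lens, function(L) tail_restraint(L, a, b)$upper, numeric(1))
  expect_true(all(diff(ub) > 0))
  expect_error(tail_restraint(0, a, b), ">= 1")
})

test_that("restraint files are byte-stable and round-trip", {
  rs <- rbind(distance_restraint("B", 5, "A", 100, 0, 30),
              distance_restraint("A", 2, "B", 9, 10, 25, source = "TAIL"))
  class(rs) <- c("restraint_set", "data.frame")
  f1 <- withr::local_tempfile(fileext = ".tbl")
  f2 <- withr::local_tempfile(fileext = ".tbl")
  write_tbl(rs, f1); write_tbl(rs, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl(
    "assign \\(segid B and resid 5 and name CA\\) \\(segid A and resid 100 and name CA\\) 30.0 30.0 0.0",
    readLines(f1))))
  back <- read_tbl(f1)
  o <- order(rs$chain_a, rs$resid_a)
  expect_equal(back[, c("chain_a", "resid_a", "chain_b", "resid_b",
                        "lower", "upper")],
               rs[o, c("chain_a", "resid_a", "chain_b", "resid_b",
                       "lower", "upper")],
               ignore_attr = TRUE)
})

test_that("circular map export carries one labelled row per link", {
  g <- gen_xl_table(13)
  net <- replicate_filter(xl_network(g$table), 2)
  map <- export_circular_map(net)
  expect_equal(nrow(map), nrow(net$links))
  expect_true(all(map$class %in% c("intra", "inter")))
  expect_true(all(map$support_class %in% c("solid", "dashed")))
})

test_that("non-reactive crosslink endpoints raise a warning, not an error", {
  seqs <- c(TIR1 = "MKSTYAAAAA", IAA7 = "MASTKAAAAA")
  df <- make_xl_df(list("TIR1", 6, "IAA7", 5, "rep1"))  # TIR1 pos6 = A
  net <- xl_network(load_xl_table(df))
  expect_warning(bad <- check_reactive_residues(net, seqs), "non-reactive")
  expect_equal(bad$residue, 6L)
})
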