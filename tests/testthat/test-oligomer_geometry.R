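test_that("default monomer layout is centred on the pore and ordered counter-clockwise", {
  lay <- monomer_layout()
  expect_equal(unname(colMeans(lay$domain_centers)), c(0, 0))
  expect_identical(rownames(lay$domain_centers), c("A", "B", "C", "D"))
  ang <- atan2(lay$domain_centers[, 2], lay$domain_centers[, 1])
  expect_true(all(diff(ang %% (2 * pi)) > 0))  # A, B, C, D counter-clockwise
  d <- as.matrix(dist(lay$domain_centers))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(monomer_layout(domain_radius = 0), "domain_radius")
  expect_error(monomer_layout(domain_radius = -1), "domain_radius")
  expect_error(monomer_layout(linker_reach = c(N_term = 0, C_term = 1, loop3 = 1)),
               "linker_reach")
})

test_that("CD dimer places the C and D domains of both monomers at the interface", {
  arr <- build_arrangement("dimer", "CD")
  expect_length(arr$poses, 2L)
  dd <- arrangement_domains(arr)
  # interface midline: the perpendicular bisector between the two monomer
  # centroids
  cent <- sapply(split(dd, dd$monomer), function(d) c(mean(d$x), mean(d$y)))
  mid <- rowMeans(cent)
  nvec <- cent[, 2] - cent[, 1]
  dist_to_midline <- abs((dd$x - mid[1]) * nvec[1] + (dd$y - mid[2]) * nvec[2]) /
    sqrt(sum(nvec^2))
  nearest4 <- dd[order(dist_to_midline)[1:4], ]
  expect_setequal(paste0(nearest4$domain, nearest4$monomer),
                  c("C1", "D1", "C2", "D2"))
})

test_that("tetramer with central MPM D puts the four D copies nearest the centroid", {
  arr <- build_arrangement("tetramer", "D")
  expect_length(arr$poses, 4L)
  dd <- arrangement_domains(arr)
  r <- sqrt(dd$x^2 + dd$y^2)
  expect_true(all(dd$domain[order(r)[1:4]] == "D"))
})

test_that("monomer arrangement is the identity pose", {
  lay <- monomer_layout()
  arr <- build_arrangement("monomer", layout = lay)
  dd <- arrangement_domains(arr)
  expect_equal(cbind(dd$x, dd$y), unname(lay$domain_centers))
  expect_error(build_arrangement("monomer", spec = "CD"), "NULL")
})

test_that("invalid interface and centre labels are rejected", {
  expect_error(build_arrangement("dimer", "AC"), "spec")
  expect_error(build_arrangement("dimer", NULL), "spec")
  expect_error(build_arrangement("tetramer", "E"), "spec")
})

test_that("domain disks of different monomers do not interpenetrate", {
  for (arr in standard_arrangements()) {
    expect_lt(oligostate:::max_domain_overlap(arr), 1e-8)
  }
})

test_that("feasibility verdicts reproduce the published structural analysis", {
  exps <- trk1_bifc_experiments()
  # CD/DC dimer with both fragments at C-termini can complement
  v <- predict_bifc(build_arrangement("dimer", "CD"), exps$cc)
  expect_identical(v$value, "feasible")
  expect_lte(v$min_pair_distance, v$threshold)
  # AB/BA dimer cannot complement in any C-terminal-containing experiment
  ab <- build_arrangement("dimer", "AB")
  for (ex in exps[c("vcn_vnc", "vnn_vcc", "cc")]) {
    expect_identical(predict_bifc(ab, ex)$value, "infeasible")
  }
  # a single monomer can close the intramolecular reporter
  v <- predict_bifc(build_arrangement("monomer"), trk1_intramolecular_experiment())
  expect_identical(v$value, "feasible")
  # but an intermolecular experiment needs two monomers
  v <- predict_bifc(build_arrangement("monomer"), exps$cc)
  expect_identical(v$value, "infeasible")
  expect_identical(v$min_pair_distance, Inf)
  # DA/AD dimer with both fragments at N-termini is within reach but blocked
  # by the loop conflict between MPMs C and D
  v <- predict_bifc(build_arrangement("dimer", "DA"), exps$nn)
  expect_identical(v$value, "blocked")
  expect_lte(v$min_pair_distance, v$threshold)
})

test_that("the computed table is complete and matches the reference on all 45 cells", {
  t0 <- Sys.time()
  tab <- compute_feasibility_table()
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_identical(nrow(tab$entries), 45L)
  ref <- reported_feasibility_table()
  M <- feasibility_matrix(tab)
  Mr <- feasibility_matrix(ref)
  expect_identical(M[rownames(Mr), colnames(Mr)], Mr)
  # loop-3 insertion discriminates exactly BC/CB, CD/DC, tetramers A and B
  loop3 <- M[, "loop3"]
  expect_setequal(names(loop3)[loop3 == "feasible"],
                  c("dimer_BC", "dimer_CD", "tetramer_A", "tetramer_B"))
})

test_that("empty inputs to the table builder are rejected", {
  expect_error(compute_feasibility_table(list(), trk1_bifc_experiments()),
               "non-empty")
})

test_that("feasibility is monotone in linker reach", {
  base <- feasibility_matrix(compute_feasibility_table())
  for (fac in c(0.5, 1.5)) {
    lay <- monomer_layout(linker_reach = fac * oligostate:::.default_linker_reach())
    m <- feasibility_matrix(compute_feasibility_table(
      standard_arrangements(lay), trk1_bifc_experiments()))
    m <- m[rownames(base), colnames(base)]
    if (fac > 1) {
      expect_false(any(base == "feasible" & m == "infeasible"))
    } else {
      expect_false(any(base == "infeasible" & m == "feasible"))
    }
  }
})

test_that("verdicts are invariant under permuting monomer indices", {
  exps <- trk1_bifc_experiments()
  for (id in c("dimer_CD", "tetramer_B")) {
    arr <- standard_arrangements()[[id]]
    perm <- arr
    perm$poses <- rev(arr$poses)
    for (ex in exps) {
      v1 <- predict_bifc(arr, ex)
      v2 <- predict_bifc(perm, ex)
      expect_identical(v1$value, v2$value)
      expect_equal(v1$min_pair_distance, v2$min_pair_distance)
    }
  }
})

test_that("cyclic MPM relabelling maps CD-interface distances onto DA-interface distances", {
  lay <- monomer_layout()
  relab <- relabel_layout(lay, shift = -1L)
  exps <- trk1_bifc_experiments()
  arr_cd_rel <- build_arrangement("dimer", "CD", layout = relab)
  arr_da <- build_arrangement("dimer", "DA", layout = lay)
  for (ex in exps) {
    expect_equal(predict_bifc(arr_cd_rel, ex)$min_pair_distance,
                 predict_bifc(arr_da, ex)$min_pair_distance,
                 tolerance = 1e-10)
  }
})

test_that("feasibility tables round-trip through TSV and export to JSON", {
  tab <- compute_feasibility_table()
  tsv <- tempfile(fileext = ".tsv")
  write_feasibility_table(tab, tsv, "tsv")
  back <- read_feasibility_table(tsv)
  expect_identical(feasibility_matrix(back), feasibility_matrix(tab))
  js <- tempfile(fileext = ".json")
  write_feasibility_table(tab, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(parsed$provenance, "computed")
  expect_identical(nrow(parsed$entries), 45L)
})

test_that("experiments require one VN-like and one VC-like fragment", {
  expect_error(fusion_experiment("bad", list(
    list(construct = 1L, anchor = "N_term", fragment = "VN"),
    list(construct = 2L, anchor = "C_term", fragment = "VN")
  )), "VN-like")
  expect_error(predict_bifc(
    build_arrangement("dimer", "CD"),
    fusion_experiment("odd", list(
      list(construct = 1L, anchor = "N_term", fragment = "VN"),
      list(construct = 2L, anchor = "loop3", fragment = "GC")
    ))
  ), NA)  # loop3 anchor exists in the default layout
})
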