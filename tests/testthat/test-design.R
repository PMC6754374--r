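test_that("design specifications validate tone counts and targets", {
  expect_error(design_spec("centered", 4), "odd")
  expect_error(design_spec("enclosing_edge", 5), "even")
  expect_error(design_spec("enclosing_balanced", 3), "even")
  expect_error(design_spec("centered", 5, r = 1), "r")
  expect_error(design_spec("centered", 5, r = -1.2), "r")
  expect_error(design_spec("centered", 1), "at least 2")
  expect_s3_class(design_spec("centered", 5, r = 0.25, f_T = 1000),
                  "design_spec")
})

test_that("neighbor placement solves the implicit overlap equation", {
  # coinciding edges, both directions, frozen from the affine closed form
  expect_equal(place_neighbor(934, "up", 0), 1066.6755, tolerance = 1e-6)
  expect_equal(place_neighbor(1000, "down", 0), 874.1529, tolerance = 1e-6)
  # matches the oracle across targets, directions and normalizations
  for (r in c(-0.25, 0, 0.25)) {
    for (dir in c("up", "down")) {
      for (norm in c("min", "max")) {
        got <- place_neighbor(2000, dir, r, normalization = norm)
        expect_equal(got, oracle_place(2000, dir, r, norm),
                     tolerance = 1e-9,
                     label = sprintf("r=%g %s %s", r, dir, norm))
      }
    }
  }
  expect_error(place_neighbor(1000, "up", r = 1), "r")
  expect_error(place_neighbor(-5, "up"), "positive")
})

test_that("placed neighbors achieve the requested overlap under hearing loss", {
  nt <- ag_notch4k()
  for (f0 in c(1500, 3000, 5000)) {
    for (r in c(-0.25, 0, 0.25)) {
      f_up <- place_neighbor(f0, "up", r, nt)
      rd <- rd_erb_pair(band_at(f0, nt, warn = FALSE),
                        band_at(f_up, nt, warn = FALSE), "min")
      expect_equal(rd, r, tolerance = 1e-6)
      f_dn <- place_neighbor(f0, "down", r, nt)
      rd2 <- rd_erb_pair(band_at(f_dn, nt, warn = FALSE),
                         band_at(f0, nt, warn = FALSE), "min")
      expect_equal(rd2, r, tolerance = 1e-6)
    }
  }
})

test_that("tinnitus-centered designs pin the middle tone and meet the target", {
  al <- design_centered(design_spec("centered", 5, r = 0, f_T = 1000))
  expect_equal(al$tones[3], 1000)
  expect_equal(al$tones, oracle_centered(1000, 5, 0), tolerance = 1e-9)
  # frozen oracle values for the coinciding-edge chain
  expect_equal(al$tones, c(761.1940, 874.1529, 1000, 1140.2058, 1296.4087),
               tolerance = 1e-6)
  expect_true(all(abs(al$achieved_rd$rd) < 1e-6))

  # 25% overlap contracts the set, 25% gap spreads it
  al_o <- design_centered(design_spec("centered", 5, r = 0.25, f_T = 1000))
  al_g <- design_centered(design_spec("centered", 5, r = -0.25, f_T = 1000))
  expect_true(all(abs(al_o$achieved_rd$rd - 0.25) < 1e-6))
  expect_true(all(abs(al_g$achieved_rd$rd + 0.25) < 1e-6))
  expect_lt(diff(range(al_o$tones)), diff(range(al$tones)))
  expect_gt(diff(range(al_g$tones)), diff(range(al$tones)))
  ratios_o <- al_o$tones / 1000
  ratios_g <- al_g$tones / 1000
  expect_true(all(abs(ratios_o - 1) <= abs(ratios_g - 1)))
})

test_that("enclosing-edge designs put both inner band edges at f_T", {
  spec <- design_spec("enclosing_edge", 4, r = 0, f_T = 1000)
  al <- design_enclosing_edge(spec)
  expect_equal(al$tones[2], 937.0765, tolerance = 1e-6)
  expect_equal(al$tones[3], 1070.1029, tolerance = 1e-6)
  expect_equal(al$tones[1], 817.6735, tolerance = 1e-6)
  expect_equal(al$tones, oracle_enclosing_edge(1000, 4, 0), tolerance = 1e-9)
  b2 <- band_at(al$tones[2])
  b3 <- band_at(al$tones[3])
  expect_equal(b2$b, 1000, tolerance = 1e-6)
  expect_equal(b3$a, 1000, tolerance = 1e-6)
  # the inner pair is pinned at rd = 0 regardless of r
  al_r <- design_enclosing_edge(design_spec("enclosing_edge", 4, r = 0.25,
                                            f_T = 1000))
  inner <- which(!al_r$achieved_rd$governed_by_r)
  expect_equal(al_r$achieved_rd$rd[inner], 0, tolerance = 1e-6)
  outer <- which(al_r$achieved_rd$governed_by_r)
  expect_equal(al_r$achieved_rd$rd[outer], rep(0.25, 2), tolerance = 1e-6)
})

test_that("balanced enclosing designs center the tinnitus band exactly", {
  spec <- design_spec("enclosing_balanced", 4, r = 0, f_T = 1000)
  al <- design_enclosing_balanced(spec)
  expect_equal(al$tones[2:3], c(930.3043, 1062.5581), tolerance = 1e-5)
  expect_equal(al$tones, oracle_enclosing_balanced(1000, 4, 0),
               tolerance = 1e-9)
  expect_lt(abs(al$balance_residual), 1e-6)
  b <- band_at(al$tones)
  expect_equal((b$a[2] + b$b[3]) / 2, 1000, tolerance = 1e-6)

  # balancing shifts the whole alignment below the edge-pinned variant
  edge <- design_enclosing_edge(design_spec("enclosing_edge", 4, r = 0,
                                            f_T = 1000))
  expect_true(all(al$tones < edge$tones))
  # with inner overlap the enclosing interval tightens symmetrically
  al_o <- design_enclosing_balanced(
    design_spec("enclosing_balanced", 4, r = 0.25, f_T = 1000))
  expect_gt(al_o$tones[2], al$tones[2])
  expect_lt(al_o$tones[3], al$tones[3])
  expect_lt(abs(al_o$balance_residual), 1e-6)

  # generic n: innermost pair carries the balancing condition
  al6 <- design_enclosing_balanced(
    design_spec("enclosing_balanced", 6, r = 0, f_T = 2000))
  b6 <- band_at(al6$tones)
  expect_equal((b6$a[3] + b6$b[4]) / 2, 2000, tolerance = 1e-6)
  expect_equal(al6$tones, oracle_enclosing_balanced(2000, 6, 0),
               tolerance = 1e-9)
})

test_that("centered ratios approach unity as the tinnitus frequency rises", {
  grid <- exp(seq(log(250), log(10000), length.out = 15))
  ratios <- t(vapply(grid, function(ft)
    design_centered(design_spec("centered", 5, r = 0, f_T = ft))$tones / ft,
    numeric(5)))
  for (j in c(1, 2)) expect_true(all(diff(ratios[, j]) > 0))  # below, rising
  for (j in c(4, 5)) expect_true(all(diff(ratios[, j]) < 0))  # above, falling
  expect_true(all(ratios[, c(1, 2)] < 1) && all(ratios[, c(4, 5)] > 1))
})

test_that("a flat loss widens the designed tone span", {
  span <- function(ag) {
    al <- design_centered(design_spec("centered", 5, r = 0, f_T = 2000), ag)
    diff(range(al$tones))
  }
  expect_gt(span(ag_flat40()), span(ag_flat0()))
})

test_that("alignment verification flags perturbations and disorder", {
  nt <- ag_notch4k()
  al <- design_centered(design_spec("centered", 5, r = 0.25, f_T = 3000), nt)
  v <- verify_alignment(al, nt)
  expect_lt(v$max_rd_residual, 1e-6)
  expect_true(v$ordering_ok)
  expect_length(v$violations, 0)

  tweaked <- al
  tweaked$tones[4] <- tweaked$tones[4] + 10
  v2 <- verify_alignment(tweaked, nt)
  expect_gt(v2$max_rd_residual, 1e-3)
  expect_true(any(grepl("rd residual", v2$violations)))

  swapped <- al
  swapped$tones <- rev(swapped$tones)
  v3 <- verify_alignment(swapped, nt)
  expect_false(v3$ordering_ok)
  expect_true(any(grepl("increasing", v3$violations)))

  off_center <- al
  off_center$tones[3] <- off_center$tones[3] + 1
  v4 <- verify_alignment(off_center, nt)
  expect_false(v4$centered_ok)
})

test_that("designs outside the supported frequency band carry warnings", {
  al <- design_centered(design_spec("centered", 5, r = -0.25, f_T = 14000))
  expect_true(any(grepl("erb_formula_range", al$warnings)))
})
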