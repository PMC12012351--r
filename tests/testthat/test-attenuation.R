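test_that("element MAC lookup is exact at grid nodes and log-log between them", {
  tab <- element_table("O")
  # nodes are returned bit-identically
  expect_identical(element_mac(tab, tab$energies), tab$mac)
  # between nodes: straight line in log-log space, checked at the geometric
  # midpoint of every adjacent node pair against a directly coded interpolant
  for (i in seq_len(length(tab$energies) - 1)) {
    e_mid <- sqrt(tab$energies[i] * tab$energies[i + 1])
    lx <- log(tab$energies[c(i, i + 1)]); ly <- log(tab$mac[c(i, i + 1)])
    oracle <- exp(ly[1] + (ly[2] - ly[1]) *
                    (log(e_mid) - lx[1]) / (lx[2] - lx[1]))
    expect_equal(element_mac(tab, e_mid), oracle, tolerance = 1e-12)
  }
  expect_error(element_mac(tab, 5), "outside tabulated span")
  expect_error(element_mac(tab, 300), "outside tabulated span")
  expect_error(element_table("Xx"), "no attenuation table")
})

test_that("mixture rule reduces to the element for single-element materials", {
  al <- ct_material("aluminium", c(Al = 1), 2.699)
  ee <- c(25, 50, 70, 125)
  expect_equal(mixture_mac(al, ee), element_mac(element_table("Al"), ee))
})

test_that("material invariants are enforced", {
  expect_error(ct_material("bad", c(H = 0.5, O = 0.4), 1), "sum to")
  expect_error(ct_material("bad", c(H = -0.1, O = 1.1), 1), "\\[0, 1\\]")
  expect_error(ct_material("bad", c(H = 0.111894, O = 0.888106), -1),
               "density")
  expect_error(ct_material("bad", c(0.5, 0.5), 1), "named")
})

test_that("water MAC matches published compound reference values", {
  # published total-attenuation values for liquid water (cm^2/g), compound
  # tabulation -- independent of the package's element tables
  ref <- c("40" = 0.2683, "60" = 0.2059, "80" = 0.1837,
           "100" = 0.1707, "150" = 0.1505)
  w <- ctqa_material("water")
  for (e in names(ref)) {
    expect_equal(mixture_mac(w, as.numeric(e)), unname(ref[e]),
                 tolerance = 0.005)
  }
})

test_that("LAC is density times MAC and homogeneous in density", {
  w <- ctqa_material("water")  # density exactly 1
  expect_equal(material_lac(w, 70)$value, mixture_mac(w, 70))
  w2 <- ct_material("dense water", w$fractions, 2)
  expect_equal(lac_value(w2, 70), 2 * lac_value(w, 70))
  expect_equal(material_lac(w, 70)$rel_uncertainty, 0.02)
})

test_that("solution construction follows the additive-mass model exactly", {
  w <- ctqa_material("water")
  expect_identical(make_solution(w, "I", 0), w)
  s <- make_solution(w, "I", 10)
  expect_equal(s$density, 1.010)
  expect_equal(s$fractions[["I"]], 0.010 / 1.010, tolerance = 1e-12)
  # mass conservation and normalization across both series
  for (series in c("iodine", "calcium")) {
    mats <- insert_series(series)
    conc <- attr(mats, "concentrations")
    el <- attr(mats, "solute")
    for (i in seq_along(mats)) {
      expect_equal(sum(mats[[i]]$fractions), 1, tolerance = 1e-9)
      if (conc[i] > 0) {
        expect_equal(mats[[i]]$fractions[[el]] * mats[[i]]$density,
                     conc[i] / 1000, tolerance = 1e-12)
      }
    }
  }
  expect_error(make_solution(w, "I", -1), "concentration")
  expect_error(make_solution(w, "Qq", 5), "no attenuation table")
})

test_that("solution LAC rises with concentration and MAC falls with energy", {
  evmi <- c(40, 60, 70, 90, 110, 130)
  ca <- insert_series("calcium")
  for (e in evmi) {
    lacs <- vapply(ca, lac_value, numeric(1), energy = e)
    expect_true(all(diff(lacs) > 0))
  }
  # MAC strictly decreasing over the VMI range (iodine K-edge lies below it)
  fine <- seq(40, 130, by = 5)
  for (m in c(list(ctqa_material("water"), ctqa_material("blood")),
              insert_series("iodine"), insert_series("calcium"))) {
    expect_true(all(diff(mixture_mac(m, fine)) < 0))
  }
})

test_that("materials round-trip through a YAML definitions file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    water = list(density = 1.0,
                 fractions = list(H = 0.111894, O = 0.888106)),
    bone_ish = list(density = 1.5,
                    fractions = list(H = 0.05, O = 0.6, Ca = 0.35))), path)
  mats <- load_materials(path)
  expect_named(mats, c("water", "bone_ish"))
  expect_equal(lac_value(mats$water, 70), lac_value(ctqa_material("water"), 70))
  # invalid files are rejected by the invariant checks
  yaml::write_yaml(list(bad = list(density = 1,
                                   fractions = list(H = 0.7, O = 0.1))), path)
  expect_error(load_materials(path), "sum to")
})
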