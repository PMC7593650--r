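test_that("matched-force step selection picks the closest step", {
  h <- data.frame(step = 1:3, applied = 1:3, reaction = c(0.10, 0.25, 0.40))
  expect_equal(select_step(h, 0.3), 2)
  expect_equal(select_step(h, 0.40), 3)                 # exact match
  expect_equal(select_step(data.frame(step = 1:2, applied = 1:2,
                                      reaction = c(0.2, 0.4)), 0.3), 1)  # tie
  expect_error(select_step(data.frame(step = integer(), applied = numeric(),
                                      reaction = numeric())), "empty")
})

# a minimal hand-built solution + mesh for the summary oracle tests:
# 8 slave nodes on a line, unit tributary areas
fake_solution <- function(pressures, xs = seq_along(pressures)) {
  n <- length(pressures)
  mesh <- structure(list(
    nodes = cbind(xs, 0, 0), elems = matrix(rep(1L, 4), 1),
    region = "tibia_cartilage", body = "tibia",
    node_sets = list(), facet_sets = list(
      femoral_cartilage_surface = cbind(n1 = 1L, n2 = 2L, n3 = 3L, owner = 1L)),
    edge_length = 1, tissues = "tibia_cartilage", body_map = NULL),
    class = "tet_mesh")
  sol <- structure(list(steps = list(list(
    step = 1L, applied = 1, u = NULL, stress = NULL, von_mises = NULL,
    contact = list(c1 = list(nodes = seq_len(n), pressure = pressures,
                             in_contact = pressures > 0,
                             tributary = rep(1, n),
                             force_z = -pressures)),
    reaction = sum(pressures), reaction_vec = NULL)),
    protocol = NULL, pair_names = "c1"), class = "fe_solution")
  list(mesh = mesh, sol = sol)
}

test_that("uniform contact pressure gives mean = peak = p", {
  fx <- fake_solution(rep(2.5, 8))
  part <- structure(list(split_x = 100, surface_nodes = 1:8,
                         labels = rep("lateral", 8)),
                    class = "condyle_partition")
  s <- pressure_summary(fx$sol, fx$mesh, 1, part)
  lat <- s[s$condyle == "lateral", ]
  expect_equal(lat$mean_pressure, 2.5)
  expect_equal(lat$peak_pressure, 2.5)
  expect_equal(lat$contact_area, 8)
  expect_false(lat$no_contact)
  med <- s[s$condyle == "medial", ]
  expect_true(med$no_contact)
  expect_equal(med$peak_pressure, 0)
})

test_that("isolated high-pressure points are excluded from the peak", {
  # a cluster at 2 MPa and one isolated node at 10 MPa far away
  p <- c(2, 2, 2, 2, 0, 0, 0, 10)
  xs <- c(1, 2, 3, 4, 5, 6, 7, 50)
  fx <- fake_solution(p, xs)
  part <- structure(list(split_x = 100, surface_nodes = 1:8,
                         labels = rep("lateral", 8)),
                    class = "condyle_partition")
  s <- pressure_summary(fx$sol, fx$mesh, 1, part, k_neighbors = 3,
                        radius_factor = 3)
  lat <- s[s$condyle == "lateral", ]
  expect_equal(lat$peak_pressure, 2)
  # the isolated node still counts towards the mean over contacting nodes
  expect_equal(lat$mean_pressure, mean(p[p > 0]))
  # histogram counts sum to the number of contacting nodes
  h <- attr(s, "histograms")$lateral
  expect_equal(sum(h$counts), sum(p > 0))
})

test_that("summary matches a brute-force recomputation", {
  set.seed(21)
  p <- round(runif(40, 0, 4), 2)
  p[sample(40, 10)] <- 0
  xs <- runif(40, 0, 10)
  fx <- fake_solution(p, xs)
  part <- structure(list(split_x = 5, surface_nodes = 1:40,
                         labels = ifelse(xs < 5, "lateral", "medial")),
                    class = "condyle_partition")
  s <- pressure_summary(fx$sol, fx$mesh, 1, part, k_neighbors = 0)
  for (cond in c("lateral", "medial")) {
    sel <- (xs < 5) == (cond == "lateral")
    pc <- p[sel & p > 0]
    row <- s[s$condyle == cond, ]
    expect_equal(row$mean_pressure, mean(pc), tolerance = 1e-12)
    expect_equal(row$peak_pressure, max(pc), tolerance = 1e-12)
    expect_equal(row$n_contact, length(pc))
  }
})

test_that("condyle partition splits the articular surface sagittally", {
  # two facet clusters at x ~ 0 and x ~ 2
  nodes <- rbind(cbind(runif(20, 0, 0.5), runif(20), runif(20)),
                 cbind(runif(20, 1.8, 2.3), runif(20), runif(20)))
  fs <- cbind(n1 = 1:38, n2 = 2:39, n3 = 3:40, owner = 1L)
  mesh <- structure(list(nodes = nodes, elems = matrix(1:4, 1),
                         region = "femur_cartilage", body = "femur",
                         node_sets = list(),
                         facet_sets = list(femoral_cartilage_surface = fs),
                         edge_length = 0.1, tissues = "femur_cartilage",
                         body_map = NULL), class = "tet_mesh")
  part <- partition_condyles(mesh)
  expect_gt(part$split_x, 0.5)
  expect_lt(part$split_x, 1.8)
  expect_equal(sum(part$labels == "lateral"), 20)
  # a single-cluster surface fails with an informative error
  mesh1 <- mesh
  mesh1$facet_sets$femoral_cartilage_surface <- fs[1:18, ]
  expect_error(partition_condyles(mesh1, split_x = 10), "empty")
})

test_that("model comparison reports percent differences against the baseline", {
  mk <- function(mean_l, peak_l, mean_m = 1, peak_m = 2) {
    data.frame(condyle = c("lateral", "medial"), n_contact = c(5L, 5L),
               mean_pressure = c(mean_l, mean_m),
               peak_pressure = c(peak_l, peak_m),
               contact_area = c(1, 1), step = 1L, reaction = 0.3,
               no_contact = FALSE)
  }
  summaries <- list(generic_one_thickness = mk(2.7, 5.6),
                    individual = mk(1.7, 3.2))
  tab <- compare_models(summaries,
                        baseline = c(lateral = "generic_one_thickness",
                                     medial = "generic_one_thickness"))
  ind <- tab[tab$variant == "individual" & tab$condyle == "lateral", ]
  expect_equal(ind$pct_mean, 100 * (1.7 - 2.7) / 2.7, tolerance = 1e-12)
  expect_lt(abs(ind$pct_mean - (-37)), 1)     # -37% to the printed precision
  base <- tab[tab$variant == "generic_one_thickness" & tab$condyle == "lateral", ]
  expect_equal(base$pct_mean, 0)
  expect_equal(base$pct_peak, 0)
  # identical summaries give all-zero percent differences
  tab2 <- compare_models(list(a = mk(2, 4), b = mk(2, 4)),
                         baseline = c(lateral = "a", medial = "a"))
  expect_true(all(abs(tab2$pct_mean) < 1e-12))
  # missing variants are marked absent
  tab3 <- compare_models(list(a = mk(2, 4), b = NULL),
                         baseline = c(lateral = "a", medial = "a"))
  expect_true(tab3$absent[tab3$variant == "b"][1])
})

test_that("frequency plots are written to file", {
  hl <- list(modelA = list(lateral = list(breaks = seq(0, 1, 0.2),
                                          counts = c(5, 3, 2, 1, 1)),
                           medial = list(breaks = numeric(), counts = integer())))
  f <- tempfile(fileext = ".svg")
  plot_pressure_frequency(hl, "lateral", path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
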