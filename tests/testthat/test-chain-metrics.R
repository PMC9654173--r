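test_that("chain height: marker formulas, zero clamp, window mean", {
  topo <- instantiate_chains(build_grid(40, 20))  # 3 x 3 chains
  traj <- static_traj(topo)
  # template markers z = {R0: 30, R1: 25, R3: 10} -> h1 = 20, h2 = 15
  expect_equal(chain_height(traj, topo, 1), 20)

  # collapsed chain: both candidate heights negative -> clamped to 0
  mk <- brushfoul:::chain_marker_rows(topo, 1)
  tr2 <- traj
  tr2$coords[mk["marker_CTR_R0"], 3, 1] <- 5
  tr2$coords[mk["marker_CIN_R1"], 3, 1] <- 7
  tr2$coords[mk["marker_CTR_R3"], 3, 1] <- 10
  expect_equal(chain_height(tr2, topo, 1), 0)

  # scripted alternating heights 20/10 over 100 frames -> mean 15
  nat <- nrow(topo$atoms)
  coords <- array(rep(topo$coords, 100), c(nat, 3, 100))
  even <- seq(2, 100, by = 2)
  coords[mk["marker_CTR_R0"], 3, even] <- 20  # h1 = 10
  coords[mk["marker_CIN_R1"], 3, even] <- 15  # h2 = 5
  tr3 <- new_traj(coords, 10, topo$box)
  expect_equal(chain_height(tr3, topo, 1), 15)

  # missing marker is an error naming chain and role
  broken <- topo
  broken$atoms$role[broken$atoms$role == "marker_CTR_R0" &
                      broken$atoms$chain_id == 2] <- "polymer_backbone"
  tb <- static_traj(broken)
  expect_error(chain_height(tb, broken, 2), "chain 2.*marker_CTR_R0")
})

test_that("chain RMSF: closed forms and degenerate windows", {
  topo <- instantiate_chains(build_grid(40, 20))
  nat <- nrow(topo$atoms)
  side <- !is.na(topo$atoms$chain_id) & topo$atoms$chain_id == 1 &
    !topo$atoms$anchored & !is.na(topo$atoms$group_id)

  # two-state oscillator: every side-group atom at z +/- a about its mean
  a <- 1.7
  coords <- array(rep(topo$coords, 10), c(nat, 3, 10))
  coords[side, 3, seq(1, 9, by = 2)] <-
    coords[side, 3, seq(1, 9, by = 2)] + a
  coords[side, 3, seq(2, 10, by = 2)] <-
    coords[side, 3, seq(2, 10, by = 2)] - a
  tr <- new_traj(coords, 10, topo$box)
  expect_equal(chain_rmsf(tr, topo, 1), a)

  # static trajectory: zero for every chain
  tr0 <- static_traj(topo, n_frames = 4)
  for (cid in 1:9) expect_equal(chain_rmsf(tr0, topo, cid), 0)

  # rigidly translated chain (identical per frame after shift of the
  # whole frame set? no: per-frame identical coordinates) -> RMSF 0
  shifted <- array(rep(topo$coords, 6), c(nat, 3, 6))
  shifted[, 1, ] <- shifted[, 1, ] + 3.2  # same shift in all frames
  expect_equal(chain_rmsf(new_traj(shifted, 10, topo$box), topo, 1), 0)

  expect_error(chain_rmsf(static_traj(topo, 1), topo, 1), "2 frames")
})

test_that("chain hydration: boundary inclusion, guards, scripted counts", {
  topo <- instantiate_chains(build_grid(20, 20))  # 2 x 2 chains
  ox <- brushfoul:::role_idx(topo, "sulfonate_O", chain_id = 1)[1]
  oxp <- topo$coords[ox, ]
  add_water_at <- function(tp, o_pos, h1_off, h2_off = c(0, 0, 0.9)) {
    wa <- data.frame(serial = max(tp$atoms$serial) + 1:3,
                     role = c("water_O", "water_H", "water_H"),
                     chain_id = NA_integer_, group_id = NA_character_,
                     anchored = FALSE, charge = 0L,
                     donor = c(FALSE, TRUE, TRUE), acceptor = FALSE,
                     tacticity = NA_character_)
    new_topo(rbind(tp$atoms, wa[, colnames(tp$atoms)]),
             rbind(tp$coords, rbind(o_pos, o_pos + h1_off, o_pos + h2_off)),
             grid = tp$grid, box = tp$box)
  }
  # one H at 2.9 A (inside), the other at 3.1 A (outside) -> count 1
  t1 <- add_water_at(topo, oxp + c(10, 0, 0),
                     h1_off = c(-10 + 2.9, 0, 0) + (oxp - oxp),
                     h2_off = c(-10 + 3.1, 0, 0))
  # place H atoms absolutely: first H 2.9 from oxygen, second 3.1
  t1$coords[nrow(t1$coords) - 1, ] <- oxp + c(2.9, 0, 0)
  t1$coords[nrow(t1$coords), ] <- oxp + c(3.1, 0, 0)
  expect_equal(chain_hydration(static_traj(t1), t1, 1), 1)

  # exactly at the cutoff is inside (inclusive convention)
  t1$coords[nrow(t1$coords), ] <- oxp + c(3.0, 0, 0)
  expect_equal(chain_hydration(static_traj(t1), t1, 1), 2)

  # no waters: an error, not silently zero
  expect_error(chain_hydration(static_traj(topo), topo, 1), "no water")

  # 50 waters with both hydrogens in the shell of chain 1 -> mean 100
  t50 <- topo
  for (k in 1:50)
    t50 <- add_water_at(t50, oxp + c(0.4, 0, 0),
                        h1_off = c(0.5, 0, 0), h2_off = c(0, 0.5, 0))
  expect_equal(chain_hydration(static_traj(t50, 3), t50, 1), 100)
  # an H near several oxygens of the chain still counts once
  expect_lte(chain_hydration(static_traj(t50), t50, 1), 100)
  # per-group breakdown is exposed
  pg <- chain_hydration(static_traj(t50), t50, 1, per_group = TRUE)
  expect_equal(pg$chain, 100)
  expect_equal(sum(pg$by_group >= 100), 1L)
})

test_that("adding a water inside the shell never decreases hydration", {
  fx <- random_fixture(n_frames = 5, seed = 7, water_count = 4)
  base <- chain_hydration(fx$trajectory, fx$topology, 1)
  ox <- brushfoul:::role_idx(fx$topology, c("ester_O", "sulfonate_O"),
                             chain_id = 1)[1]
  tp <- fx$topology
  wa <- data.frame(serial = max(tp$atoms$serial) + 1:3,
                   role = c("water_O", "water_H", "water_H"),
                   chain_id = NA_integer_, group_id = NA_character_,
                   anchored = FALSE, charge = 0L,
                   donor = c(FALSE, TRUE, TRUE), acceptor = FALSE,
                   tacticity = NA_character_)
  tp2 <- new_topo(rbind(tp$atoms, wa[, colnames(tp$atoms)]), rbind(
    tp$coords, rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))),
    grid = tp$grid, box = tp$box)
  co <- fx$trajectory$coords
  big <- array(NA_real_, dim(co) + c(3, 0, 0))
  big[seq_len(dim(co)[1]), , ] <- co
  for (f in seq_len(dim(co)[3]))
    big[dim(co)[1] + 1:3, , f] <- rbind(co[ox, , f] + c(1, 0, 0),
                                        co[ox, , f] + c(1.5, 0, 0),
                                        co[ox, , f] + c(1, 0.5, 0))
  tr2 <- new_traj(big, 10, tp$box)
  expect_gte(chain_hydration(tr2, tp2, 1), base)
})

test_that("height translation behaviour and oracle equivalence", {
  fx <- random_fixture(n_frames = 20, seed = 13)
  traj <- fx$trajectory; topo <- fx$topology
  w <- seq_len(20)
  for (cid in 1:2) {
    expect_equal(chain_height(traj, topo, cid, w),
                 oracle_height(traj, topo, cid, w), tolerance = 1e-10)
    expect_equal(chain_rmsf(traj, topo, cid, w),
                 oracle_rmsf(traj, topo, cid, w), tolerance = 1e-10)
    expect_equal(chain_hydration(traj, topo, cid, w),
                 oracle_hydration(traj, topo, cid, w), tolerance = 1e-10)
  }
  # xy translation leaves height untouched; rigid z shift of the whole
  # chain moves both marker differences equally, so height shifts only
  # when the clamp is inactive
  t2 <- traj
  t2$coords[, 1, ] <- t2$coords[, 1, ] + 11
  t2$coords[, 2, ] <- t2$coords[, 2, ] - 4
  expect_equal(chain_height(t2, topo, 1, w), chain_height(traj, topo, 1, w))
  t3 <- traj
  idx <- which(!is.na(topo$atoms$chain_id) & topo$atoms$chain_id == 1)
  t3$coords[idx, 3, ] <- t3$coords[idx, 3, ] + 50
  expect_equal(chain_height(t3, topo, 1, w), chain_height(traj, topo, 1, w))
})

test_that("chain_profile covers every chain with grid coordinates", {
  topo <- tiny_topology()
  sim <- generate_trajectory(topo, scenario_spec("static", n_frames = 3,
                                                 water_count = 10, seed = 1))
  for (metric in c("height", "rmsf", "hydration")) {
    prof <- chain_profile(sim$trajectory, sim$topology, metric)
    expect_equal(nrow(prof), 4L)
    expect_setequal(prof$chain_id, 1:4)
    expect_true(all(prof$value >= 0))
  }
})
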