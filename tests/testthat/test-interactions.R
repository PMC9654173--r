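# Hand-built two-chain fixture with a foulant pair at a controllable
# distance from polymer charge sites.
contact_fixture <- function(d_neg_N = 30, d_pos_SO = 30, d_H_O = 30,
                            n_frames = 4) {
  atoms <- data.frame(
    serial = 1:8,
    role = c("ammonium_N", "sulfonate_O", "ester_O",
             "ammonium_N", "sulfonate_O",
             "foulant_neg_atom", "foulant_pos_atom", "foulant_polar_H"),
    chain_id = c(1L, 1L, 1L, 2L, 2L, NA, NA, NA),
    group_id = c("R0", "R0", "R0", "R0", "R0", NA, NA, NA),
    anchored = FALSE,
    charge = c(1L, -1L, 0L, 1L, -1L, -1L, 1L, 0L),
    donor = c(rep(FALSE, 7), TRUE),
    acceptor = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    tacticity = NA_character_)
  coords <- rbind(
    c(0, 0, 10),            # N chain 1
    c(50, 0, 10),           # SO chain 1
    c(0, 20, 10),           # ester O chain 1
    c(20, 0, 10),           # N chain 2
    c(20, 3, 10),           # SO chain 2 (3 A from N chain 2, cross-pair
    c(0, 0, 10 + d_neg_N),  # foulant neg above N chain 1
    c(50, 0, 10 + d_pos_SO),# foulant pos above SO chain 1
    c(0, 20, 10 + d_H_O))   # polar H above ester O chain 1
  topo <- new_topo(atoms, coords, box = c(100, 100, 100))
  list(topology = topo, trajectory = static_traj(topo, n_frames))
}

test_that("electrostatic contacts: sign rule, inclusive cutoff, occurrence", {
  fx <- contact_fixture(d_neg_N = 4.0)  # exactly at the cutoff: inclusive
  tab <- electrostatic_contacts(fx$trajectory, fx$topology)
  row <- tab[tab$role_i == "foulant_neg_atom" & tab$chain_j == 1 &
               tab$role_j == "ammonium_N", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$percent, 100)

  # like-charged pair at 1 A never appears
  fx2 <- contact_fixture()
  fx2$trajectory$coords[7, , ] <- fx2$trajectory$coords[4, , ] +
    c(0, 0, 1)  # foulant pos 1 A above ammonium N: same sign
  tab2 <- electrostatic_contacts(fx2$trajectory, fx2$topology)
  expect_false(any(tab2$role_i == "foulant_pos_atom" &
                     tab2$role_j == "ammonium_N"))

  # 50% scheduled contact -> 50.0, and the per-chain surface statistic
  fx3 <- contact_fixture(n_frames = 10)
  fx3$trajectory$coords[6, 3, 1:5] <- 10 + 3.5  # within cutoff frames 1-5
  tab3 <- electrostatic_contacts(fx3$trajectory, fx3$topology)
  expect_equal(tab3$percent[tab3$role_i == "foulant_neg_atom" &
                              tab3$chain_j == 1], 50)
  expect_equal(attr(tab3, "mean_contacts_per_chain"), (5 / 10) / 2)

  bare <- contact_fixture()
  bare$topology$atoms$charge <- 0L
  expect_error(electrostatic_contacts(bare$trajectory, bare$topology),
               "charged")
})

test_that("hydrogen bonds: distance-only criterion at 2.4 A", {
  fx <- contact_fixture(d_H_O = 2.3)
  tab <- hydrogen_bonds(fx$trajectory, fx$topology)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$percent, 100)
  expect_equal(tab$role_j, "ester_O")

  fx2 <- contact_fixture(d_H_O = 2.5)
  expect_equal(nrow(hydrogen_bonds(fx2$trajectory, fx2$topology)), 0L)

  # scheduled 1 frame in 10 -> 10%
  fx3 <- contact_fixture(n_frames = 10)
  fx3$trajectory$coords[8, 3, 4] <- 10 + 2.0
  tab3 <- hydrogen_bonds(fx3$trajectory, fx3$topology)
  expect_equal(tab3$percent, 10)

  nod <- contact_fixture()
  nod$topology$atoms$donor <- FALSE
  expect_error(hydrogen_bonds(nod$trajectory, nod$topology), "donor")
})

test_that("inter-chain contacts exclude same-chain pairs", {
  fx <- contact_fixture()
  tab <- interchain_contacts(fx$trajectory, fx$topology)
  # N(chain2)-SO(chain2) at 3 A is same-chain: excluded; the only
  # cross-chain pair within 4 A is N(chain1)... none. Check the rule:
  expect_true(all(tab$chain_i != tab$chain_j))
  # put SO of chain 2 within 4 A of N of chain 1
  fx$trajectory$coords[5, , ] <- c(0, 3, 10)
  tab2 <- interchain_contacts(fx$trajectory, fx$topology)
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$percent, 100)
  expect_equal(c(tab2$chain_i, tab2$chain_j), c(1L, 2L))

  single <- contact_fixture()
  keep <- which(single$topology$atoms$chain_id %in% c(1L, NA))
  topo1 <- new_topo(single$topology$atoms[keep, ],
                    single$topology$coords[keep, ], box = c(100, 100, 100))
  expect_error(interchain_contacts(static_traj(topo1, 2), topo1),
               "at least 2 chains")
})

test_that("neglect floor removes strictly-below rows only", {
  tab <- data.frame(atom_i = 1:3, atom_j = 4:6,
                    percent = c(4.9, 5.0, 80))
  class(tab) <- c("occurrence_table", "data.frame")
  out <- apply_neglect_floor(tab)
  expect_equal(out$percent, c(5.0, 80))
  expect_equal(nrow(apply_neglect_floor(tab[0, ])), 0L)

  set.seed(21)
  big <- data.frame(atom_i = 1:100, atom_j = 101:200,
                    percent = runif(100, 0, 10))
  class(big) <- c("occurrence_table", "data.frame")
  filt <- apply_neglect_floor(big)
  expect_equal(filt$percent, big$percent[big$percent >= 5])
})

test_that("occurrence percentages obey window invariances", {
  fx <- random_fixture(n_frames = 12, seed = 31)
  traj <- fx$trajectory; topo <- fx$topology
  tab <- electrostatic_contacts(traj, topo, cutoff = 8)
  # frame reordering within the window
  perm <- sample(1:12)
  tab_p <- electrostatic_contacts(traj, topo, window = perm, cutoff = 8)
  expect_table_matches_oracle(tab_p, tab[, c("atom_i", "atom_j", "percent")])
  # duplicating the window leaves every percentage unchanged
  dup <- new_traj(traj$coords[, , c(1:12, 1:12)], 10, traj$box)
  tab_d <- electrostatic_contacts(dup, topo, cutoff = 8)
  expect_table_matches_oracle(tab_d, tab[, c("atom_i", "atom_j", "percent")])
  # cutoff monotonicity: smaller-cutoff table is a subset, percentages <=
  lo <- electrostatic_contacts(traj, topo, cutoff = 5)
  key <- function(d) paste(d$atom_i, d$atom_j)
  m <- match(key(lo), key(tab))
  expect_false(anyNA(m))
  expect_true(all(lo$percent <= tab$percent[m] + 1e-12))
})

test_that("all occurrence tables match the brute-force oracle", {
  fx <- random_fixture(n_frames = 10, seed = 57)
  traj <- fx$trajectory; topo <- fx$topology; a <- topo$atoms
  w <- 1:10
  el <- electrostatic_contacts(traj, topo, cutoff = 8)
  fi <- which(startsWith(a$role, "foulant") & a$charge != 0)
  pi_ <- which(!is.na(a$chain_id) & a$charge != 0)
  expect_table_matches_oracle(el, oracle_occurrence(
    traj, topo, fi, pi_, 8, w,
    keep = function(i, j) a$charge[i] * a$charge[j] < 0))

  hb <- hydrogen_bonds(traj, topo, cutoff = 6)
  don <- which(a$role == "foulant_polar_H")
  acc <- which(!is.na(a$chain_id) & a$acceptor)
  expect_table_matches_oracle(hb, oracle_occurrence(traj, topo, don, acc,
                                                    6, w))

  ic <- interchain_contacts(traj, topo, cutoff = 12)
  nn <- which(a$role == "ammonium_N")
  so <- which(a$role == "sulfonate_O")
  expect_table_matches_oracle(ic, oracle_occurrence(
    traj, topo, nn, so, 12, w,
    keep = function(i, j) a$chain_id[i] != a$chain_id[j]))
})

test_that("residue-level aggregation keeps the maximum pair percentage", {
  tab <- data.frame(
    atom_i = c(6L, 6L, 7L), atom_j = c(1L, 2L, 2L),
    role_i = c("foulant_neg_atom", "foulant_neg_atom", "foulant_pos_atom"),
    role_j = "x", chain_i = NA_integer_, chain_j = c(1L, 1L, 2L),
    type = "electrostatic", frames = c(1L, 8L, 3L),
    percent = c(10, 80, 30))
  class(tab) <- c("occurrence_table", "data.frame")
  agg <- aggregate_by_residue(tab)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$percent[agg$atom_i == 6], 80)
})
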