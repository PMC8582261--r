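# Structural observables: element RMSD traces, H-bonds, SASA, dihedrals,
# pairwise RMSD maps.

test_that("element RMSD traces behave on constructed trajectories", {
  ref <- test_chain(12)
  el <- element_definition("tail", residues = 7:12)
  copies <- md_trajectory(rep(list(ref), 4))
  expect_equal(element_rmsd_trace(copies, ref, el)$rmsd, rep(0, 4))

  # linear interpolation towards the reference decreases strictly
  far <- ref
  set.seed(2)
  far$xyz <- ref$xyz + matrix(rnorm(36), 12, 3)
  traj <- make_interpolated_trajectory(far, ref, 6)
  tr <- element_rmsd_trace(traj, ref, el)
  expect_true(all(diff(tr$rmsd) < 0))

  # an element covering everything equals the global Calpha RMSD
  all_el <- element_definition("all", residues = 1:12)
  got <- element_rmsd_trace(traj, ref, all_el, mode = "calpha")$rmsd
  want <- vapply(
    seq_len(6),
    function(i) rmsd_fitted(get_frame(traj, i), ref), 0
  )
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(
    element_rmsd_trace(traj, ref, element_definition("none", 99)),
    "no atoms"
  )
})

water_dimer <- function(oo = 2.8) {
  # donor water O1-H pointing straight at acceptor O2
  md_structure(
    rbind(
      c(0, 0, 0), # O donor
      c(0.96, 0, 0), # H on the O-O axis
      c(-0.24, 0.93, 0), # second H
      c(oo, 0, 0) # O acceptor
    ),
    atom_names = c("O", "H1", "H2", "O"),
    residue_ids = c(1, 1, 1, 2),
    elements = c("O", "H", "H", "O")
  )
}

test_that("hydrogen-bond counting applies the distance and angle criterion", {
  w <- water_dimer(2.8)
  don <- atom_selection(1)
  acc <- atom_selection(4)
  expect_equal(hbond_count(w, don, acc), 1L)
  # stretched past 3.5 A: no bond
  expect_equal(hbond_count(water_dimer(3.6), don, acc), 0L)
  # rotate the whole dimer: invariant
  rot <- w
  rot$xyz <- w$xyz %*% t(rotation_about_z(1.1)) + 5
  expect_equal(hbond_count(rot, don, acc), 1L)
  # donor without hydrogens is a topology error
  bare <- md_structure(rbind(c(0, 0, 0), c(2.8, 0, 0)),
    atom_names = c("O", "O"), elements = c("O", "O"), residue_ids = c(1, 2)
  )
  expect_error(hbond_count(bare, atom_selection(1), atom_selection(2)), "hydrogen")
})

test_that("hydrogen-bond counts match brute-force enumeration on random systems", {
  oracle_hbonds <- function(s, don, acc, dmax = 3.5, amax = 30) {
    xyz <- s$xyz
    hyd <- which(s$atoms$element == "H")
    n <- 0L
    for (d in don) {
      hs <- hyd[vapply(hyd, function(h) sqrt(sum((xyz[h, ] - xyz[d, ])^2)) <= 1.25, TRUE)]
      for (a in acc) {
        if (a == d) next
        r <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
        if (r > dmax) next
        ok <- FALSE
        for (h in hs) {
          v1 <- xyz[h, ] - xyz[d, ]
          v2 <- xyz[a, ] - xyz[d, ]
          ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
          if (ang <= amax) ok <- TRUE
        }
        if (ok) n <- n + 1L
      }
    }
    n
  }
  for (seed in 1:5) {
    set.seed(seed)
    no <- 6
    oxy <- matrix(runif(3 * no, 0, 6), no, 3)
    hx <- oxy + matrix(rnorm(3 * no, sd = 0.4), no, 3)
    hx <- oxy + 0.96 * (hx - oxy) / sqrt(rowSums((hx - oxy)^2))
    s <- md_structure(rbind(oxy, hx),
      atom_names = rep(c("O", "H"), each = no),
      elements = rep(c("O", "H"), each = no),
      residue_ids = rep(seq_len(no), 2)
    )
    don <- atom_selection(1:no)
    expect_equal(
      hbond_count(s, don, don),
      oracle_hbonds(s, 1:no, 1:no)
    )
  }
})

test_that("SASA matches the analytic sphere and obeys additivity bounds", {
  lone <- md_structure(matrix(0, 1, 3), elements = "C")
  got <- sasa_shrake_rupley(lone, n_points = 960)
  expect_equal(as.numeric(got), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # two coincident equal atoms: SASA of a single sphere
  two <- md_structure(matrix(0, 2, 3), elements = "C")
  expect_equal(
    as.numeric(sasa_shrake_rupley(two)),
    4 * pi * (1.7 + 1.4)^2,
    tolerance = 0.02 * 4 * pi * 3.1^2
  )
  # SASA grows monotonically with separation until additivity
  seps <- c(0.5, 1.5, 3, 5, 6.5)
  areas <- vapply(seps, function(d) {
    s <- md_structure(rbind(c(0, 0, 0), c(d, 0, 0)), elements = "C")
    as.numeric(sasa_shrake_rupley(s))
  }, 0)
  expect_true(all(diff(areas) >= -1e-9))
  expect_equal(areas[5], 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # multi-atom SASA never exceeds the sum of isolated spheres
  set.seed(3)
  blob <- md_structure(matrix(rnorm(15, sd = 2), 5, 3), elements = "C")
  expect_lt(
    as.numeric(sasa_shrake_rupley(blob)),
    5 * 4 * pi * 3.1^2 + 1e-9
  )
  expect_error(
    sasa_shrake_rupley(md_structure(matrix(0, 1, 3), elements = "XX")),
    "radius"
  )
})

# build a 5-residue backbone with prescribed phi/psi using internal
# coordinates (NeRF-style placement)
build_backbone <- function(phi, psi, omega = 180) {
  place <- function(a, b, c, r, theta, chi) {
    # place atom at distance r from c, angle theta (b-c-new), dihedral chi
    # (a-b-c-new)
    bc <- c - b
    bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    n <- c(
      ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
      ab[1] * bc[2] - ab[2] * bc[1]
    )
    n <- n / sqrt(sum(n^2))
    m <- c(
      n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
      n[1] * bc[2] - n[2] * bc[1]
    )
    th <- theta * pi / 180
    ch <- chi * pi / 180
    d <- r * (-cos(th) * bc + sin(th) * (cos(ch) * m + sin(ch) * n))
    c + d
  }
  nres <- length(phi)
  coords <- matrix(0, 3 * nres, 3)
  # seed the first residue
  coords[1, ] <- c(0, 0, 0) # N
  coords[2, ] <- c(1.46, 0, 0) # CA
  coords[3, ] <- place(c(-1, 1, 0), coords[1, ], coords[2, ], 1.52, 111, psi[1] + 180) # C placed arbitrarily then psi set by next N
  coords[3, ] <- c(2.0, 1.4, 0)
  for (i in 2:nres) {
    b <- 3 * (i - 1)
    coords[b + 1, ] <- place(coords[b - 2, ], coords[b - 1, ], coords[b, ], 1.33, 114, psi[i - 1]) # N: dihedral N-CA-C-N = psi
    coords[b + 2, ] <- place(coords[b - 1, ], coords[b, ], coords[b + 1, ], 1.46, 123, omega) # CA: omega
    coords[b + 3, ] <- place(coords[b, ], coords[b + 1, ], coords[b + 2, ], 1.52, 110, phi[i]) # C: dihedral C-N-CA-C = phi
  }
  md_structure(coords,
    atom_names = rep(c("N", "CA", "C"), nres),
    residue_ids = rep(seq_len(nres), each = 3),
    elements = rep(c("N", "C", "C"), nres)
  )
}

test_that("backbone dihedrals invert the construction angles", {
  s <- build_backbone(phi = rep(-57, 5), psi = rep(-47, 5))
  for (res in 2:4) {
    ang <- backbone_dihedrals(s, res)
    expect_equal(ang$phi, -57, tolerance = 1e-6)
    expect_equal(ang$psi, -47, tolerance = 1e-6)
  }
  flat <- build_backbone(phi = rep(180, 4), psi = rep(180, 4))
  ang <- backbone_dihedrals(flat, 3)
  expect_equal(abs(ang$phi), 180, tolerance = 1e-6)
  expect_equal(abs(ang$psi), 180, tolerance = 1e-6)
  # chain termini: NA flags, not errors
  ends <- backbone_dihedrals(s, 1)
  expect_true(is.na(ends$phi))
  expect_false(is.na(ends$psi))
})

test_that("the dihedral closed form matches an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(6)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- pathmetad:::dihedral_(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- bio3d::torsion.xyz(as.vector(t(pts)))
    expect_equal(got, as.numeric(want), tolerance = 1e-6)
  }
})

test_that("pairwise RMSD maps are consistent with displacement_metrics", {
  sys <- make_two_state_system(10, 3, 4, seed = 3)
  traj <- make_interpolated_trajectory(sys$state_a, sys$state_b, 5)
  M <- pairwise_rmsd_map(traj, traj)
  expect_equal(diag(M), rep(0, 5), tolerance = 1e-8)
  expect_equal(M, t(M), tolerance = 1e-10)
  for (i in c(1, 3)) {
    for (j in c(2, 5)) {
      want <- displacement_metrics(get_frame(traj, i), get_frame(traj, j),
        fit = TRUE
      )$rmsd
      expect_equal(M[i, j], want, tolerance = 1e-10)
    }
  }
  # single-frame sets give a 1 x 1 matrix with the row argmin attribute
  M1 <- pairwise_rmsd_map(sys$state_a, sys$state_b)
  expect_equal(dim(M1), c(1L, 1L))
  expect_equal(attr(M, "row_argmin"), 1:5)
})
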