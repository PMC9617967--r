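test_that("aligned lateral neighbors count 1 per occupied adjacent column", {
  cols <- rep(list(rep(3L, 10)), 13)
  lat <- small_lattice(cols)
  # both neighbors occupied at height 5
  expect_equal(lateral_neighbor_count(lat, 6, 5), 2)
  # tip site above both neighbors
  cols2 <- cols
  cols2[[6]] <- rep(3L, 11)
  lat2 <- small_lattice(cols2)
  expect_equal(lateral_neighbor_count(lat2, 6, 11), 0)
  # one-sided occupancy
  cols3 <- cols
  cols3[[5]] <- rep(3L, 12)
  lat3 <- small_lattice(cols3)
  expect_equal(lateral_neighbor_count(lat3, 6, 11), 1)
  expect_equal(lateral_neighbor_count(lat3, 6, 13), 0)
  expect_equal(lateral_neighbor_count(lat3, 6, 10), 2)
})

test_that("seam contacts contribute half neighbors with the 1.5-dimer stagger", {
  # PF 13 at height h sees PF 1 at h+1 and h+2, 0.5 each
  cols <- rep(list(integer(0)), 13)
  cols[[1]] <- rep(3L, 6)   # occupied heights 1..6
  cols[[13]] <- rep(3L, 8)
  lat <- small_lattice(cols)
  # height 4 on PF 13: PF 1 occupied at 5 and 6 -> 0.5 + 0.5; PF 12 empty
  expect_equal(lateral_neighbor_count(lat, 13, 4), 1)
  # height 5: PF 1 occupied at 6 but not 7 -> 0.5
  expect_equal(lateral_neighbor_count(lat, 13, 5), 0.5)
  # height 7: PF 1 ends at 6 -> 0
  expect_equal(lateral_neighbor_count(lat, 13, 7), 0)
  # the mirrored view: PF 1 at height h sees PF 13 at h-2 and h-1
  expect_equal(lateral_neighbor_count(lat, 1, 3), 1)   # PF13 occ at 1,2
  expect_equal(lateral_neighbor_count(lat, 1, 1), 0)   # would need heights -1, 0
})

test_that("neighbor counts agree with an independent interval-overlap oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n_pf <- sample(c(2, 3, 13), 1)
    cols <- lapply(seq_len(n_pf), function(p) {
      rep(3L, sample(0:12, 1))
    })
    lat <- small_lattice(cols, n_pf = n_pf)
    for (k in 1:15) {
      p <- sample(n_pf, 1)
      h <- sample(1:14, 1)
      expect_equal(lateral_neighbor_count(lat, p, h),
                   overlap_neighbor_count(lat, p, h),
                   info = sprintf("n_pf=%d pf=%d h=%d", n_pf, p, h))
    }
  }
})

test_that("seam bond contributions are symmetric between the two views", {
  cols <- rep(list(integer(0)), 13)
  cols[[1]] <- rep(1L, 10)
  cols[[13]] <- rep(2L, 10)
  cols[[2]] <- rep(3L, 0)
  cols[[12]] <- rep(3L, 0)
  lat <- small_lattice(cols)
  # contribution of a lone dimer on column q at height hq to the count at
  # (p, hp); the seam bond must look the same from both sides
  pair_contribution <- function(p, hp, q, hq) {
    cls <- rep(list(integer(0)), 13)
    cls[[q]] <- rep(3L, hq)  # occupied up to hq; only hq can touch (p, hp)
    lateral_neighbor_count(small_lattice(cls), p, hp) -
      lateral_neighbor_count(small_lattice({
        cls[[q]] <- rep(3L, hq - 1)
        cls
      }), p, hp)
  }
  for (h in c(1, 4, 9)) {
    for (cc in c(1, 2, 5, 10)) {
      expect_equal(pair_contribution(13, h, 1, cc),
                   pair_contribution(1, cc, 13, h))
    }
  }
})

test_that("fractional counts arise only at the seam; interior sites are integral", {
  set.seed(42)
  cols <- lapply(1:13, function(p) rep(3L, sample(3:9, 1)))
  lat <- small_lattice(cols)
  for (p in 2:12) {
    for (h in 1:10) {
      expect_true(lateral_neighbor_count(lat, p, h) %in% c(0, 1, 2))
    }
  }
})

test_that("a uniform-height lattice gives identical tip-site counts away from the seam", {
  cols <- rep(list(rep(3L, 7)), 13)
  lat <- small_lattice(cols)
  counts <- vapply(2:12, function(p) lateral_neighbor_count(lat, p, 8),
                   numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("add_dimer appends at the tip and preserves order", {
  lat <- small_lattice(list(rep(1L, 10), integer(0), rep(2L, 3)))
  lat2 <- add_dimer(lat, 1, 2)
  expect_equal(length(lat2$columns[[1]]), 11)
  expect_equal(lat2$columns[[1]][11], 2L)
  # empty column
  lat3 <- add_dimer(lat, 2, 3)
  expect_equal(lat3$columns[[2]], 3L)
  # two successive adds preserve order
  lat4 <- add_dimer(add_dimer(lat, 3, 1), 3, 2)
  expect_equal(lat4$columns[[3]], c(2L, 2L, 2L, 1L, 2L))
  expect_error(add_dimer(lat, 1, 7), "species")
  expect_error(add_dimer(lat, 99, 1), "range")
})

test_that("cascade removal takes the dimer and everything above it", {
  lat <- small_lattice(list(rep(3L, 12)))
  expect_equal(cascade_removal_set(lat, 1, 11), c(11L, 12L))
  expect_equal(cascade_removal_set(lat, 1, 12), 12L)
  expect_equal(cascade_removal_set(lat, 1, 1), 1:12)
  expect_equal(length(remove_cascade(lat, 1, 11)$columns[[1]]), 10)
  expect_equal(length(remove_cascade(lat, 1, 1)$columns[[1]]), 0)
  expect_error(cascade_removal_set(lat, 1, 13), "occupied")
  expect_error(cascade_removal_set(lat, 1, 0), "occupied")
})

test_that("columns stay gap-free under random add/remove sequences", {
  set.seed(7)
  lat <- small_lattice(rep(list(rep(3L, 5)), 4), n_pf = 4)
  for (i in 1:300) {
    p <- sample(4, 1)
    L <- length(lat$columns[[p]])
    if (L > 0 && stats::runif(1) < 0.4) {
      lat <- remove_cascade(lat, p, sample(L, 1))
    } else {
      lat <- add_dimer(lat, p, sample(3, 1))
    }
    expect_true(mtkmc:::lattice_is_valid(lat))
    # occupied heights are exactly 1..L by construction of the columns
    expect_true(all(vapply(lat$columns, is.integer, logical(1))))
  }
})
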