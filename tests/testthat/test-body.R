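test_that("body construction counts follow the chain formulas", {
  b <- build_snake()
  expect_equal(b$n_joints, 14)
  expect_equal(b$n_muscles, 26)
  expect_equal(build_snake(3)$n_joints, 2)
  expect_equal(build_snake(3)$n_muscles, 2)
  expect_equal(build_snake(10)$n_muscles, 16)
  for (n in 3:20) {
    bb <- build_snake(n)
    expect_equal(bb$n_joints, n - 1)
    expect_equal(bb$n_muscles, 2 * (n - 2))
    expect_true(all(bb$muscles$joint_b == bb$muscles$joint_a + 1))
  }
  expect_error(build_snake(2), class = "serpens_invalid_parameter")
})

test_that("muscle lengths are mirror-symmetric around the straight pose", {
  b <- build_snake()
  straight <- list(theta = rep(0, 14))
  expect_equal(muscle_length(straight, b), rep(b$params$L0, 26))

  phi <- 0.3
  th <- rep(0, 14)
  th[3] <- th[4] <- phi
  L <- muscle_length(list(theta = th), b)
  left3 <- which(b$muscles$side == "left" & b$muscles$joint_a == 3)
  right3 <- which(b$muscles$side == "right" & b$muscles$joint_a == 3)
  expect_lt(L[left3], b$params$L0)
  expect_gt(L[right3], b$params$L0)
  expect_equal(L[left3] - b$params$L0, -(L[right3] - b$params$L0))
  # extreme bend matches the closed form L0 * (1 -+ kappa * phi)
  expect_equal(L[left3], b$params$L0 * (1 - b$params$kappa * phi))

  # negating all angles swaps left and right lengths exactly
  Lneg <- muscle_length(list(theta = -th), b)
  ns <- b$n_muscles / 2
  expect_equal(L[1:ns], Lneg[(ns + 1):(2 * ns)])
})

test_that("motor map squashes and scales commands", {
  b <- build_snake()
  mm0 <- motor_map(rep(0, 26), b)
  expect_equal(mm0$u, rep(0, 26))
  expect_equal(mm0$rest_len, rep(b$params$L0, 26))
  mm_inf <- motor_map(rep(1e6, 26), b)
  expect_equal(mm_inf$rest_len, rep(b$params$L0 * (1 + b$params$gain_motor), 26))
  mm1 <- motor_map(rep(1, 26), b)
  expect_equal(mm1$rest_len[1], b$params$L0 * (1 + b$params$gain_motor * tanh(1)))
})

test_that("sensory readout is proportional stretch, clipped and mirrored", {
  b <- build_snake()
  st <- serpens:::new_body_state(b)
  expect_equal(sensory_readout(st, b), rep(0, 26))

  th <- rep(0.2, 14)
  st2 <- serpens:::new_body_state(b, theta = th)
  i <- sensory_readout(st2, b)
  ns <- b$n_muscles / 2
  expect_equal(i[1:ns], -i[(ns + 1):(2 * ns)]) # antagonists mirror
  expect_true(all(abs(i) <= 2))
  # sigma * (L - L0) / L0 on an explicit length
  sigma <- b$params$sigma_sensory
  L <- muscle_length(st2, b)
  expect_equal(i, pmin(pmax(sigma * (L - b$params$L0) / b$params$L0, -2), 2))
})

test_that("zero command leaves a straight body at rest", {
  b <- build_snake()
  st <- serpens:::new_body_state(b)
  st2 <- body_step(b, st, rep(b$params$L0, 26), dt = 0.01, n_steps = 100)
  expect_equal(st2$theta, rep(0, 14), tolerance = 1e-12)
  expect_equal(unname(st2$head), c(0, 0, 0), tolerance = 1e-12)
})

test_that("a bent body relaxes monotonically under zero command", {
  b <- build_snake()
  st <- serpens:::new_body_state(b, theta = rep(0.4, 14))
  prev <- max(abs(st$theta))
  mono <- TRUE
  for (i in 1:200) {
    st <- body_step(b, st, rep(b$params$L0, 26), dt = 0.01, n_steps = 10)
    cur <- max(abs(st$theta))
    if (cur > prev + 1e-10) mono <- FALSE
    prev <- cur
  }
  expect_true(mono)
  expect_lt(prev, 0.4)
})

test_that("constant asymmetric command bends the spanned joints the right way", {
  b <- build_snake()
  st <- serpens:::new_body_state(b)
  rest <- rep(b$params$L0, 26)
  rest[1] <- b$params$L0 * 0.85 # contract first left muscle
  for (i in 1:500) st <- body_step(b, st, rest, 0.01, 10)
  expect_gt(st$theta[1], 0.05) # bends toward the contracted (left) side
  expect_gt(st$theta[2], 0.01) # second spanned joint shares less of the bend
})

test_that("traveling-wave commands produce net locomotion", {
  b <- build_snake()
  st <- serpens:::new_body_state(b)
  dt <- 0.01
  for (i in 1:5000) {
    t <- i * dt
    u <- 0.8 * sin(2 * pi * 0.5 * t - (1:13) * 0.6)
    rest <- b$params$L0 * (1 + b$params$gain_motor * c(u, -u))
    st <- body_step(b, st, rest, dt)
  }
  body_len <- b$n_links * b$params$link_len + (b$n_links - 1) * b$params$gap
  expect_gt(sqrt(sum(st$head[1:2]^2)), 0.5 * body_len)
})
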