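test_that("noiseless activity fit recovers planted coefficients exactly", {
  cks <- paste0("CK", 1:10)
  sim <- simulateSignatureResponse(400, cks, active = c(CK3 = 2, CK7 = -1),
                                   noiseSd = 0, seed = 1)
  fit <- fitActivity(sim$signatures, sim$response, lambda = 0, nPerm = 100,
                     seed = 1)
  tab <- activityTable(fit)
  expect_equal(tab$cytokine, cks)  # signature column order preserved
  expect_equal(tab$coefficient[tab$cytokine == "CK3"], 2, tolerance = 1e-8)
  expect_equal(tab$coefficient[tab$cytokine == "CK7"], -1, tolerance = 1e-8)
  expect_lt(max(abs(tab$coefficient[!tab$cytokine %in% c("CK3", "CK7")])),
            1e-8)
})

test_that("orthonormal-signature least squares is the exact identity", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))
  rownames(Q) <- sprintf("G%06d", 1:100)
  colnames(Q) <- paste0("CK", 1:6)
  S <- SignatureMatrix(Q)
  zTrue <- c(1.5, 0, -2, 0, 0.5, 0)
  y <- drop(Q %*% zTrue)
  names(y) <- rownames(Q)
  # centering does not break exact recovery of centered responses
  fit <- fitActivity(S, y - mean(y), lambda = 0, nPerm = 100, seed = 3)
  z <- activityTable(fit)$coefficient
  expect_equal(drop(crossprod(scale(Q, scale = FALSE), scale(Q, scale = FALSE)) %*% z),
               drop(crossprod(scale(Q, scale = FALSE), y - mean(y))),
               tolerance = 1e-10)
})

test_that("zero response gives zero coefficients and null p-values", {
  sim <- simulateSignatureResponse(200, paste0("CK", 1:5), seed = 4)
  y <- setNames(numeric(200), names(sim$response))
  fit <- fitActivity(sim$signatures, y, lambda = 10, nPerm = 200, seed = 5)
  tab <- activityTable(fit)
  expect_equal(tab$coefficient, rep(0, 5))
  expect_equal(tab$perm_z, rep(0, 5))
  expect_equal(tab$perm_p, rep(1, 5))
})

test_that("ridge shrinks monotonically and response scaling scales coefficients", {
  sim <- simulateSignatureResponse(300, paste0("CK", 1:8),
                                   active = c(CK2 = 2), noiseSd = 0.5,
                                   seed = 6)
  norms <- vapply(c(0, 10, 1e3, 1e5), function(lam)
    sqrt(sum(activityTable(
      fitActivity(sim$signatures, sim$response, lambda = lam, nPerm = 100,
                  seed = 7))$coefficient^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[[4]], 0.05 * norms[[1]])
  f1 <- fitActivity(sim$signatures, sim$response, lambda = 100, nPerm = 100,
                    seed = 8)
  f3 <- fitActivity(sim$signatures, 3 * sim$response, lambda = 100,
                    nPerm = 100, seed = 8)
  expect_equal(activityTable(f3)$coefficient,
               3 * activityTable(f1)$coefficient, tolerance = 1e-10)
  expect_equal(activityTable(f3)$perm_z, activityTable(f1)$perm_z,
               tolerance = 1e-8)  # z invariant under positive scaling
})

test_that("permutation p-values are calibrated under the null", {
  # null world: inactive response, many replicates; type-I error near nominal
  cks <- paste0("CK", 1:10)
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    sim <- simulateSignatureResponse(150, cks, active = numeric(),
                                     noiseSd = 1, seed = 100 + s)
    fit <- fitActivity(sim$signatures, sim$response, lambda = 100,
                       nPerm = 200, seed = 200 + s)
    p <- activityTable(fit)$perm_p
    hits <- hits + sum(p <= 0.05)
    total <- total + length(p)
  }
  expect_lte(hits / total, 1.5 * 0.05)
})

test_that("activity fit validates inputs", {
  sim <- simulateSignatureResponse(50, paste0("CK", 1:3), seed = 1)
  expect_error(fitActivity(sim$signatures, c(G000001 = 1), lambda = 0,
                           nPerm = 100, seed = 1), "overlap too small")
  yBad <- sim$response; yBad[[1]] <- NA_real_
  expect_error(fitActivity(sim$signatures, yBad, lambda = 0, nPerm = 100,
                           seed = 1), "finite")
})

test_that("differential activity flags the planted aged-only cytokine", {
  cks <- paste0("CK", 1:6)
  mk <- function(active, seedOffset) {
    lapply(c(W1 = 1, W2 = 2), function(i) {
      sim <- simulateSignatureResponse(400, cks, active = active,
                                       noiseSd = 0.1,
                                       seed = 10 * seedOffset + i)
      fitActivity(sim$signatures, sim$response, lambda = 10, nPerm = 100,
                  seed = 10 * seedOffset + i)
    })
  }
  aged <- mk(c(CK4 = 2), 1)
  young <- mk(numeric(), 2)
  da <- differentialActivity(aged, young)
  expect_true(da$elevated[da$cytokine == "CK4"])
  expect_false(any(da$elevated[da$cytokine != "CK4"] &
                     abs(da$coef_diff_W1[da$cytokine != "CK4"]) > 1))
  # identical inputs give all-zero differences
  same <- differentialActivity(aged, aged)
  expect_equal(same$coef_diff_W1, rep(0, 6))
  expect_false(any(same$elevated))  # "exceeds" is strict
  expect_error(differentialActivity(aged, young[1]), "identical timepoint")
})

test_that("source-tissue filter applies both bounds", {
  tab <- data.frame(cytokine = c("OSM", "IL6", "TGFB", "IL17"),
                    synovium = c(0.20, 0.15, 0.60, 0.004),
                    chondrocyte = c(0.000, 0.009, 0.05, 0.001))
  got <- intersectSourceFilter(c("OSM", "IL6", "TGFB", "IL17"), tab,
                               "synovium", "chondrocyte")
  expect_identical(got, c("OSM", "IL6"))  # TGFB fails target, IL17 source
  # row-scan oracle on random tables
  set.seed(9)
  for (rep in 1:5) {
    t2 <- data.frame(cytokine = sprintf("C%02d", 1:30),
                     src = runif(30, 0, 0.4), tgt = runif(30, 0, 0.03))
    want <- t2$cytokine[t2$src > 0.05 & t2$tgt < 0.01]
    expect_identical(
      intersectSourceFilter(t2$cytokine, t2, "src", "tgt"), want)
  }
  expect_error(intersectSourceFilter("NOPE", tab, "synovium", "chondrocyte"),
               "missing")
})
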