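# independent brute-force oracles used to freeze expected values

# free metal concentration by bisection on the total-metal balance
# Mt = Fe * (1 + Kb*Lt/(1 + Kb*Fe))
bisect_free_metal <- function(Kb, Lt, Mt) {
  if (Mt == 0) return(0)
  f <- function(Fe) Fe * (1 + Kb * Lt / (1 + Kb * Fe)) - Mt
  lo <- 0
  hi <- Mt
  for (i in 1:500) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # machine resolution reached
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# bound complex concentration by bisection on the 1:1 mass law
# Kb * (Pt - PL) * (Lt - PL) = PL
bisect_complex <- function(Kb, Lt, Pt) {
  ub <- min(Lt, Pt)
  if (ub == 0 || Kb == 0) return(0)
  g <- function(PL) Kb * (Pt - PL) * (Lt - PL) - PL
  lo <- 0
  hi <- ub
  for (i in 1:500) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # machine resolution reached
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.xmin)),
              label = sprintf("max rel diff %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), .Machine$double.xmin)),
                              tol))
}
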