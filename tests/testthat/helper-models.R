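# Shared fixtures, built once per test run (several derivations are
# moderately expensive symbolic computations).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# kernel internals used by white-box tests
rf_equal <- netzoom:::rf_equal
expr_to_rf <- netzoom:::expr_to_rf
rf_eval <- netzoom:::rf_eval
rf_vars <- netzoom:::rf_vars
rf_is_zero <- netzoom:::rf_is_zero
rf_subs <- netzoom:::rf_subs
rf_to_expr <- netzoom:::rf_to_expr
rf_const <- netzoom:::rf_const
rf_sub <- netzoom:::rf_sub
mvp_deg <- netzoom:::mvp_deg
rat_rank <- netzoom:::rat_rank

enzyme_setup <- function() cached("enzyme", {
  fx <- enzyme_kinetics()
  part <- fs_partition(fx$network, fast = fx$fast)
  fractions <- derive_fractions(fx$network, part, fx$schemes$two_state,
                                exact = fx$exact)
  reduced <- derive_reduced(fx$network, part, fx$schemes$two_state,
                            fractions, fx$apparent, exact = fx$exact)
  c(fx, list(part = part, fractions = fractions, reduced = reduced))
})

glucose_setup <- function() cached("glucose", {
  fx <- glucose_transport()
  part <- fs_partition(fx$network, fast = fx$fast)
  fr5 <- derive_fractions(fx$network, part, fx$schemes$five_state,
                          exact = fx$exact)
  red5 <- derive_reduced(fx$network, part, fx$schemes$five_state,
                         fr5, fx$apparent, exact = fx$exact)
  c(fx, list(part = part, fr5 = fr5, red5 = red5))
})

small_setup <- function() cached("small", {
  fx <- small_example()
  part <- fs_partition(fx$network, fast = fx$fast)
  fractions <- derive_fractions(fx$network, part, fx$schemes$two_state,
                                exact = fx$exact)
  reduced <- derive_reduced(fx$network, part, fx$schemes$two_state,
                            fractions, fx$apparent, exact = fx$exact)
  c(fx, list(part = part, fractions = fractions, reduced = reduced))
})

# span equality of two integer row bases, by exact rational rank
same_row_span <- function(A, B) {
  if (nrow(A) != nrow(B)) return(FALSE)
  B <- B[, colnames(A), drop = FALSE]
  rat_rank(A) == nrow(A) &&
    rat_rank(rbind(A, B)) == nrow(A)
}

extdata <- function(f) system.file("extdata", f, package = "netzoom")
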