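# Shared fixtures: canonical templates and small study configs.

tri_spec <- function(n = 1000L, dc = 35, ac = 10, rf = 0.5) {
  pulse_template_spec(dc, ac, rf, "triangular", n)
}

gamma_spec <- function(n = 100L, dc = 35, ac = 10, rf = 0.3) {
  pulse_template_spec(dc, ac, rf, "gamma_like", n)
}

tri_cycle <- function(n = 1000L, dc = 35, ac = 10, rf = 0.5, f = 1) {
  cardiac_cycle(make_pulse_template(tri_spec(n, dc, ac, rf)), f)
}

small_config <- function(...) {
  study_config(n_rabbits = 4L, days = c(1, 4, 7, 10, 13, 16, 19, 22, 25, 28),
               baseline_sessions = 4L, ...)
}

# closed forms for the symmetric triangular cycle (dc 35, ac 10, rise 0.5,
# F 1 s): min 30, max 40, rising-limb trapezoid 17.5, its complement 2.5
TRI_EXPECT <- list(bos = (2 - 10 / 35) * 100, bot = 50, ri = 0.25, ati = 50,
                   rr = 25 * 17.5 / 2.5, fr = 25 * 2.5 / 17.5,
                   s1 = 17.5, s2 = 2.5)
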