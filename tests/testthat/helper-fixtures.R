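# Shared fixtures, built in code.

# tiny spacer library with deterministic spacers
toy_library <- function(n_target = 2, n_control = 3) {
  base <- c("ACGTACGTACGTACGTACGT", "TTGGCCAATTGGCCAATTGG",
            "AAAACCCCGGGGTTTTACGT", "CATGCATGCATGCATGCATG",
            "GACTGACTGACTGACTGACT", "TGCATGCATGCATGCATGCA",
            "CCGGAATTCCGGAATTCCGG", "GTACGTACGTACGTACGTAC")
  n <- n_target + n_control
  stopifnot(n <= length(base))
  data.frame(strain_id = sprintf("S%02d", seq_len(n)),
             spacer = base[seq_len(n)],
             gene = c(sprintf("gene%02d", seq_len(n_target)),
                      rep("none", n_control)),
             category = c(rep("essential", n_target),
                          rep("control", n_control)),
             stringsAsFactors = FALSE)
}

# bent-rod (banana) contour: constant-width tube around a circular arc
banana_contour <- function(radius = 3, half_angle_deg = 35, width = 1,
                           n_points = 256) {
  th <- seq(-half_angle_deg, half_angle_deg, length.out = 80) * pi / 180
  cl <- cbind(radius * sin(th), radius * cos(th))
  phenoscreen:::tube_contour(cl, width / 2, n_points)
}

# deeply constricted dividing cell: two lobes of the given width joined by
# a narrow neck
dumbbell_contour <- function(total_length = 4, width = 1, neck = 0.5,
                             n_points = 256) {
  r <- width / 2
  cl_len <- total_length - width
  mid <- cl_len / 2
  hw <- 0.35
  rfun <- function(s) {
    out <- rep(r, length(s))
    dip <- abs(s - mid) < hw
    out[dip] <- r - (r - neck / 2) * cos(pi * (s[dip] - mid) / (2 * hw))^2
    out
  }
  phenoscreen:::tube_contour(cbind(seq(0, cl_len, length.out = 200), 0),
                             rfun, n_points)
}

# brute-force upper-tail hypergeometric probability by enumerating all
# C(N, n) draws (independent oracle for small N)
hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_cat <- colSums(draws <= K)  # items 1..K form the category
  mean(in_cat >= k)
}

# analytic spherocylinder volume
sphero_volume <- function(length, width) {
  r <- width / 2
  pi * r^2 * (length - width) + (4 / 3) * pi * r^3
}
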