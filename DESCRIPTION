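Package: jdeconv
Title: Scalar Coupling Extraction by Multiplet Structure Deconvolution of 1D NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated extraction of scalar coupling constants from first-order
    multiplets in 1D NMR spectra by multiplet structure deconvolution. A multiplet
    is modelled as the convolution of a line shape with stick patterns F(J) of its
    couplings; convolving with the alternating-sign inverse series M(J*) collapses
    a splitting when the trial value J* matches a true J. The side-to-side
    (left-to-right / right-to-left) recursion implements this convolution in O(n),
    and symmetry or half-integral quality functions scanned over J* locate the
    couplings, largest first. Supports coupling partners with spin > 1/2
    (1:1:1 triplets, 1:1:1:1 quartets, ...), degenerate couplings, mild
    second-order "roof" effects with estimation of the coupling partner's chemical
    shift, sub-linewidth couplings, and partially overlapping multiplets. Includes
    a synthetic multiplet generator, validation by reconstruction, JCAMP-DX and
    two-column text input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
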