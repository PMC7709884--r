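Package: maldiHDX
Title: Isotopic-Envelope Deconvolution and Kinetics for MALDI-MS
        Hydrogen/Deuterium Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Analysis of hydrogen/deuterium exchange (HDX) measured by
        MALDI-TOF mass spectrometry on singly charged peptic peptides.
        Computes theoretical isotopic envelopes for every possible backbone
        amide deuterium incorporation count, quantifies observed isotopic
        peaks by area in fixed m/z windows, deconvolutes the observed
        envelope into the abundance fraction of molecules carrying exactly
        k deuteriums by non-negative least squares, and reports the average
        number of exchanged atoms and the average deuteration ratio.
        Uptake time courses are fitted with a single-exponential model to
        give asymptotic uptake, amplitude and apparent rate constant, and
        region-specific uptake is derived by nested-fragment subtraction.
        Includes a seeded simulator of MALDI HDX spectra and uptake series
        with known ground truth, and a command-line interface for batch
        processing of ASCII spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, pracma, minpack.lm
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'envelope.R'
    'simulate.R'
    'kinetics.R'
    'deconvolution.R'
    'cli.R'
    'fragments.R'
    'maldiHDX-package.R'
    'methods-accessors.R'
    'spectrum.R'
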