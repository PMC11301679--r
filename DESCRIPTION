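Package: metalloMS
Title: Annotation of Metal and Label Proteoforms of Cysteine-Rich Proteins
    from Native and Top-Down Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating metalloforms of cysteine-rich proteins such
    as metallothioneins from native electrospray and top-down collision-induced
    dissociation (CID) mass spectra. Enumerates candidate compositions of
    Cu(I)/Zn(II)/Cd(II) metals, N-ethylmaleimide (NEM) and iodoacetamide (IAM)
    cysteine labels and intramolecular disulfides under a cysteine-budget
    constraint; computes aggregated isotope patterns by elemental convolution
    and assigns native-MS peaks by isotope-pattern fitting with non-negative
    least-squares deconvolution of overlapping species; generates and matches
    b/y fragment ions carrying metal and label adducts, builds fragmentation
    maps, localizes labels on cysteines from fragment-ion ladders, and
    reconstructs parent stoichiometry from complementary fragment pairs;
    fits survival-yield curves on a center-of-mass collision-energy axis to
    estimate relative gas-phase stabilities (E50); and compares fragmentation
    spectra by intensity correlation and shared-ion (UpSet-style) analysis.
    Includes a deterministic simulator of native and fragment spectra with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    seqinr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
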