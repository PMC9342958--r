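# Structure files (user-supplied)

The monomer-versus-polymer superposition compares six deposited structures
that are not redistributed with this package. Download them once, e.g.:

    for id in 2MB9 6BZE 6E26 6N2P 2G7R 6GK2; do
      curl -O https://files.rcsb.org/download/$id.pdb
    done

and place the files in this directory (`.pdb`, `.ent` or `.cif`; upper- or
lower-case names). `structure_rmsd()` and the structural test in
`tests/testthat/test-acceptance.R` will pick them up from here.
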