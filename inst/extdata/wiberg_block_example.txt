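 Wiberg bond index matrix in the NAO basis:

         Atom       1       2       3       4       5       6       7       8
         ---- ----------------------------------------------------------------
      1.  P   0.0000  0.8000  0.1200  1.2100  1.3000  1.2800  0.0000  0.0000
      2.  O   0.8000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000
      3.  O   0.1200  0.0000  0.0000  0.0000  0.0000  0.0000  0.7400  0.0000
      4.  O   1.2100  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000
      5.  O   1.3000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000
      6.  O   1.2800  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000
      7.  H   0.0000  0.0000  0.7400  0.0000  0.0000  0.0000  0.0000  0.0200
      8.  O   0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0200  0.0000
      9.  N   0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000
     10.  H   0.0000  0.0000  0.0000  0.0000  0.0300  0.0000  0.0000  0.0000
     11.  Mg  0.0000  0.1000  0.0000  0.0000  0.1200  0.0000  0.0000  0.0000
     12.  O   0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000  0.0000

         Atom       9      10      11      12
         ---- --------------------------------
      1.  P   0.0000  0.0000  0.0000  0.0000
      2.  O   0.0000  0.0000  0.1000  0.0000
      3.  O   0.0000  0.0000  0.0000  0.0000
      4.  O   0.0000  0.0000  0.0000  0.0000
      5.  O   0.0000  0.0300  0.1200  0.0000
      6.  O   0.0000  0.0000  0.0000  0.0000
      7.  H   0.0000  0.0000  0.0000  0.0000
      8.  O   0.0000  0.0000  0.0000  0.0000
      9.  N   0.0000  0.7600  0.0000  0.0000
     10.  H   0.7600  0.0000  0.0000  0.0000
     11.  Mg  0.0000  0.0000  0.0000  0.0900
     12.  O   0.0000  0.0000  0.0900  0.0000

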