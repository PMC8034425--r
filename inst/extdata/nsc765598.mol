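NSC765598 N-(2,4-difluorophenyl)-2',4'-difluoro-4-hydroxybiphenyl-3-carboxamide
  screenkit fixture

 26 28  0  0  0  0  0  0  0  0999 V2000
    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    4.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    3.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    2.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    2.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    3.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0000    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0000    1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1340    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1340   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0000   -2.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.1340    4.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0000    1.5000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
    5.1340    1.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
    4.0000   -1.5000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
  1  7  1  0
  7  8  1  0
  8  9  2  0
  9 10  1  0
 10 11  2  0
 11 12  1  0
 12  7  2  0
  3 13  1  0
 13 14  2  0
 13 15  1  0
 15 16  1  0
 16 17  1  0
 17 18  2  0
 18 19  1  0
 19 20  2  0
 20 21  1  0
 21 16  2  0
  4 22  1  0
  8 23  1  0
 10 24  1  0
 17 25  1  0
 19 26  1  0
M  END
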