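! Synthetic minimal-basis reference (Gaussian dialect).
! 6-Gaussian least-squares expansions of single-zeta Slater orbitals,
! generated by scripts/make-basis-reference.R; NOT the published
! STO-6G tabulation, though constructed the same way.
!
H     0
S   6   1.00
   3.55231958E+01   9.16359542E-03
   6.51314166E+00   4.93614735E-02
   1.82214260E+00   1.68538215E-01
   6.25955208E-01   3.70562572E-01
   2.43076734E-01   4.16491251E-01
   1.00112425E-01   1.30333991E-01
****
He    0
S   6   1.00
   6.57894362E+01   9.16359686E-03
   1.20624260E+01   4.93614809E-02
   3.37463262E+00   1.68538235E-01
   1.15927749E+00   3.70562588E-01
   4.50181405E-01   4.16491227E-01
   1.85409573E-01   1.30333971E-01
****
C     0
S   6   1.00
   7.42736415E+02   9.16359657E-03
   1.36179969E+02   4.93614783E-02
   3.80982541E+01   1.68538227E-01
   1.30877797E+01   3.70562582E-01
   5.08236813E+00   4.16491237E-01
   2.09319995E+00   1.30333978E-01
SP  6   1.00
   2.61015441E+01  -1.53533983E-02   4.66286598E-03
   5.54839055E+00  -4.78715026E-02   4.14475521E-02
   1.80166689E+00  -2.89883597E-02   1.77563234E-01
   7.12071973E-01   2.52378514E-01   4.12427219E-01
   3.14013338E-01   5.85953287E-01   4.20432310E-01
   1.45068594E-01   2.46038745E-01   1.04344392E-01
****
N     0
S   6   1.00
   1.02782756E+03   9.16359666E-03
   1.88451145E+02   4.93614780E-02
   5.27218483E+01   1.68538226E-01
   1.81113794E+01   3.70562580E-01
   7.03317902E+00   4.16491238E-01
   2.89665163E+00   1.30333979E-01
SP  6   1.00
   3.35489164E+01  -1.53533996E-02   4.66286652E-03
   7.13147439E+00  -4.78715042E-02   4.14475557E-02
   2.31572404E+00  -2.89883542E-02   1.77563244E-01
   9.15242554E-01   2.52378532E-01   4.12427226E-01
   4.03608600E-01   5.85953282E-01   4.20432298E-01
   1.86460018E-01   2.46038729E-01   1.04344384E-01
****
O     0
S   6   1.00
   1.35558303E+03   9.16359680E-03
   2.48544780E+02   4.93614788E-02
   6.95338846E+01   1.68538228E-01
   2.38867682E+01   3.70562584E-01
   9.27593161E+00   4.16491236E-01
   3.82034104E+00   1.30333976E-01
SP  6   1.00
   4.46657148E+01  -1.53534004E-02   4.66286692E-03
   9.49456602E+00  -4.78715060E-02   4.14475590E-02
   3.08306440E+00  -2.89883489E-02   1.77563255E-01
   1.21851814E+00   2.52378551E-01   4.12427234E-01
   5.37348711E-01   5.85953278E-01   4.20432284E-01
   2.48245580E-01   2.46038711E-01   1.04344375E-01
****
P     0
S   6   1.00
   4.99232881E+03   9.16359795E-03
   9.15338530E+02   4.93614814E-02
   2.56078788E+02   1.68538231E-01
   8.79699850E+01   3.70562582E-01
   3.41613218E+01   4.16491231E-01
   1.40695194E+01   1.30333975E-01
SP  6   1.00
   2.59662218E+02  -1.53533993E-02   4.66286643E-03
   5.51962528E+01  -4.78715036E-02   4.14475546E-02
   1.79232628E+01  -2.89883560E-02   1.77563240E-01
   7.08380296E+00   2.52378526E-01   4.12427224E-01
   3.12385364E+00   5.85953285E-01   4.20432303E-01
   1.44316499E+00   2.46038733E-01   1.04344386E-01
SP  6   1.00
   8.34888802E+00  -6.96637241E-03  -6.59571229E-03
   2.22173492E+00  -6.62210371E-02  -1.82830983E-02
   8.19615711E-01  -1.78761554E-01   6.68427050E-02
   3.66188445E-01   1.23355990E-01   3.98583260E-01
   1.80458973E-01   7.31012666E-01   5.01738474E-01
   9.25990758E-02   3.02690913E-01   1.17803442E-01
****
S     0
S   6   1.00
   5.69466019E+03   9.16359791E-03
   1.04411030E+03   4.93614810E-02
   2.92104498E+02   1.68538230E-01
   1.00345790E+02   3.70562581E-01
   3.89672092E+01   4.16491232E-01
   1.60488494E+01   1.30333976E-01
SP  6   1.00
   3.09731954E+02  -1.53533984E-02   4.66286601E-03
   6.58395477E+01  -4.78715024E-02   4.14475519E-02
   2.13793409E+01  -2.89883600E-02   1.77563233E-01
   8.44974707E+00   2.52378512E-01   4.12427218E-01
   3.72621502E+00   5.85953287E-01   4.20432311E-01
   1.72144526E+00   2.46038747E-01   1.04344393E-01
SP  6   1.00
   1.07635374E+01  -6.96637490E-03  -6.59571400E-03
   2.86430091E+00  -6.62210534E-02  -1.82830978E-02
   1.05666345E+00  -1.78761558E-01   6.68427356E-02
   4.72096803E-01   1.23356079E-01   3.98583301E-01
   2.32650996E-01   7.31012663E-01   5.01738432E-01
   1.19380418E-01   3.02690851E-01   1.17803413E-01
****
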