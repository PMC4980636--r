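dinucleotide	property	value
AA	enthalpy	-6.6
AC	enthalpy	-10.2
AG	enthalpy	-7.6
AU	enthalpy	-5.7
CA	enthalpy	-10.5
CC	enthalpy	-12.2
CG	enthalpy	-8.0
CU	enthalpy	-7.6
GA	enthalpy	-13.3
GC	enthalpy	-14.2
GG	enthalpy	-12.2
GU	enthalpy	-10.2
UA	enthalpy	-8.1
UC	enthalpy	-13.3
UG	enthalpy	-10.5
UU	enthalpy	-6.6
AA	entropy	-18.4
AC	entropy	-26.2
AG	entropy	-19.2
AU	entropy	-15.5
CA	entropy	-27.8
CC	entropy	-29.7
CG	entropy	-19.4
CU	entropy	-19.2
GA	entropy	-35.5
GC	entropy	-34.9
GG	entropy	-29.7
GU	entropy	-26.2
UA	entropy	-22.6
UC	entropy	-35.5
UG	entropy	-27.8
UU	entropy	-18.4
AA	free_energy	-0.9
AC	free_energy	-2.1
AG	free_energy	-1.7
AU	free_energy	-0.9
CA	free_energy	-1.8
CC	free_energy	-2.9
CG	free_energy	-2.0
CU	free_energy	-1.7
GA	free_energy	-2.3
GC	free_energy	-3.4
GG	free_energy	-2.9
GU	free_energy	-2.1
UA	free_energy	-1.1
UC	free_energy	-2.3
UG	free_energy	-1.8
UU	free_energy	-0.9
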