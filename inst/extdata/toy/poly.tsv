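peptide	allele	confidence	source
TTRVASEYF	A0101	0.97	tumor_sample
RTHDPKKSF	A0101	0.97	tumor_sample
NTLSIPWWM	A0101	0.97	tumor_sample
RTVFLELVF	A0101	0.97	tumor_sample
PTLRGEFKR	A0101	0.97	tumor_sample
VTHTYFELF	A0101	0.99	tumor_sample
VTWTARNVF	A0101	0.99	tumor_sample
QTGGCMLVS	A0101	0.99	tumor_sample
APFGLHLMF	A0101	0.99	tumor_sample
VTCESTWGF	A0101	0.99	tumor_sample
STMEMTGAF	A0101	0.94	tumor_sample
CTHMNFPIF	A0101	0.94	tumor_sample
ITFSVFICF	A0101	0.94	tumor_sample
WTRCYLMAF	A0101	0.94	tumor_sample
ENPDYKNSI	B0702	0.98	tumor_sample
RNFLAYPPI	B0702	0.98	tumor_sample
INGADMPKI	B0702	0.98	tumor_sample
GNTRFELYY	B0702	0.98	tumor_sample
KNNLVDTCI	B0702	0.98	tumor_sample
TNSDVDCLI	B0702	0.98	tumor_sample
FNMTMAFMI	B0702	0.98	tumor_sample
GNQWFYRYI	B0702	0.98	tumor_sample
LNMIYKSGI	B0702	0.98	tumor_sample
QNTCAETGI	B0702	0.98	tumor_sample
DRHFVTYFI	B0702	0.98	tumor_sample
GNRVMWGAI	B0702	0.98	tumor_sample
GNECLELYI	B0702	0.98	tumor_sample
SNCLQCKII	B0702	0.98	tumor_sample
CNCIMQKTA	B0702	0.98	tumor_sample
GNRRPCWRI	B0702	0.98	tumor_sample
QNCWMVQVI	B0702	0.98	tumor_sample
RNSHIHTEI	B0702	0.98	tumor_sample
RNMYSKYWI	B0702	0.98	tumor_sample
FNRVNMDMI	B0702	0.98	tumor_sample
LNMLHCIAI	B0702	0.98	tumor_sample
NNRSKCYII	B0702	0.98	tumor_sample
WRVIVTCWI	B0702	0.98	tumor_sample
QNWMIEDKD	B0702	0.98	tumor_sample
GNKTTHESI	B0702	0.98	tumor_sample
LNIGWKTDL	B0702	0.98	tumor_sample
MNLDASNMI	B0702	0.98	tumor_sample
LNPEIYVII	B0702	0.98	tumor_sample
ANCCNKNSI	B0702	0.98	tumor_sample
VNWCGRKKI	B0702	0.98	tumor_sample
KNWPYREPI	B0702	0.98	tumor_sample
FNKYAPCYI	B0702	0.98	tumor_sample
ANYTKYFFI	B0702	0.98	tumor_sample
VNSMDVASI	B0702	0.98	tumor_sample
HNPGYHQFI	B0702	0.98	tumor_sample
MTPGSWGLI	B0702	0.98	tumor_sample
VWSDVKKDI	B0702	0.98	tumor_sample
MNPGVWHGI	B0702	0.98	tumor_sample
YNHHCRCII	B0702	0.98	tumor_sample
NNCPCCSTI	B0702	0.98	tumor_sample
QNFTWVKDI	B0702	0.98	tumor_sample
WNQWIAQFI	B0702	0.98	tumor_sample
VNSLQPETW	B0702	0.98	tumor_sample
HNGEKYWWI	B0702	0.98	tumor_sample
VNASSWRVI	B0702	0.98	tumor_sample
INGVFHNAI	B0702	0.98	tumor_sample
TNFWAQPGI	B0702	0.98	tumor_sample
WNDVHLPYI	B0702	0.98	tumor_sample
QNPVRCYWN	B0702	0.98	tumor_sample
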