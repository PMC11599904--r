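gene	gene_alt	rsid	impact	p_IND_LLA	sign_IND_LLA	p_AFR	sign_AFR	p_AMR	sign_AMR	p_EAS	sign_EAS	p_EUR	sign_EUR	p_SAS	sign_SAS
ABCB1	NA	rs2032582	Moderate	2.320e-35	-	8.933e-51	-	8.429e-22	-	8.367e-18	-	2.938e-22	-	2.817e-12	-
ADH1C	NA	rs1693482	Moderate	1.161e-09	+	6.505e-03	+	0.974	-	8.127e-04	+	3.072e-02	-	0.974	-
ADH1C	NA	rs35719513	Moderate	1.206e-06	+	1.206e-06	+	1.406e-02	+	1.206e-06	+	1.206e-06	+	1.206e-06	+
FGFR4	NA	rs1966265	Moderate	0.126	+	1.211e-20	+	2.313e-05	+	0.256	+	3.531e-09	+	3.531e-09	+
FGFR4	NA	rs351855	Moderate	1.540e-06	-	4.025e-04	-	3.699e-16	-	5.577e-17	-	1.718e-10	-	1.202e-12	-
FGFR4	NA	rs376618	Moderate	0.325	-	2.413e-10	+	1.016e-02	+	0.325	-	1.682e-06	+	2.884e-02	+
GSTA1	NA	rs1051775	High	5.466e-04	-	0.264	-	5.466e-04	-	0.052	-	6.629e-12	-	7.095e-09	-
HMMR	NA	rs299284	Moderate	1.835e-02	-	3.135e-02	-	0.235	-	1	+	3.221e-03	-	1.835e-02	-
HMMR	NA	rs299295	Moderate	0.433	-	1.191e-05	-	3.376e-02	-	1	-	2.389e-04	-	7.389e-05	-
NOS3	NOS1	rs11068428	Moderate	2.677e-15	+	6.645e-21	+	1.050e-03	+	2.365e-07	+	2.007e-14	+	3.708e-13	+
PNPLA3	NA	rs2076213	Moderate	1	-	1.064e-06	+	4.548e-02	+	4.937e-08	+	2.218e-04	+	2.218e-04	+
PNPLA3	NA	rs2294918	Moderate	3.279e-03	+	0.112	+	5.412e-03	+	2.239e-02	+	7.285e-10	+	4.072e-05	+
PNPLA3	NA	rs738409	Moderate	0.438	+	2.692e-16	+	0.244	+	4.072e-05	+	7.274e-11	+	2.777e-11	+
SERPINA6	NA	rs2228541	Moderate	0.295	+	3.591e-20	+	7.183e-06	+	0.874	+	1.903e-17	+	3.490e-09	+
SHMT1	NA	rs1979277	Moderate	7.675e-03	-	1.337e-03	-	2.504e-02	-	0.112	+	5.049e-03	-	1	-
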