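<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:attributeGroup name="shellAttrs">
    <xs:attribute name="d_max" type="xs:string" use="required"/>
    <xs:attribute name="d_min" type="xs:string" use="required"/>
    <xs:attribute name="n_obs" type="xs:string" use="required"/>
    <xs:attribute name="n_unique" type="xs:string" use="required"/>
    <xs:attribute name="n_theoretical" type="xs:string" use="required"/>
    <xs:attribute name="completeness" type="xs:string" use="required"/>
    <xs:attribute name="mean_i_over_sigma" type="xs:string" use="required"/>
    <xs:attribute name="r_merge" type="xs:string" use="required"/>
    <xs:attribute name="r_meas" type="xs:string" use="required"/>
    <xs:attribute name="multiplicity" type="xs:string" use="required"/>
  </xs:attributeGroup>

  <xs:complexType name="shellType">
    <xs:attributeGroup ref="shellAttrs"/>
  </xs:complexType>

  <xs:element name="autoproc_summary">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="branch" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="resolution_limit">
                <xs:complexType>
                  <xs:attribute name="d_min" type="xs:double" use="required"/>
                  <xs:attribute name="rule" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="all_retained"/>
                        <xs:enumeration value="both_below_boundary"/>
                        <xs:enumeration value="interpolated"/>
                        <xs:enumeration value="user_supplied"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
              <xs:element name="shell" type="shellType" maxOccurs="unbounded"/>
              <xs:element name="overall" type="shellType"/>
            </xs:sequence>
            <xs:attribute name="friedel_merged" type="xs:boolean" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="grouped_merge" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="dataset" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="verdict" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="matched"/>
                        <xs:enumeration value="re_integrated"/>
                        <xs:enumeration value="excluded"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                  <xs:attribute name="operator" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="increment" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="k" type="xs:integer" use="required"/>
                  <xs:attribute name="completeness" type="xs:string" use="required"/>
                  <xs:attribute name="mean_i_over_sigma" type="xs:string" use="required"/>
                  <xs:attribute name="multiplicity" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="reference_id" type="xs:string" use="required"/>
            <xs:attribute name="group_symbol" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="sad_triage" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="anom_shell" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="d_max" type="xs:string" use="required"/>
                  <xs:attribute name="d_min" type="xs:string" use="required"/>
                  <xs:attribute name="n_pairs" type="xs:string" use="required"/>
                  <xs:attribute name="danom_over_sigma" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="trial" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="solvent_fraction" type="xs:double" use="required"/>
                  <xs:attribute name="hand" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="original"/>
                        <xs:enumeration value="inverted"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="trigger" type="xs:boolean" use="required"/>
            <xs:attribute name="estimated_mw" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="n_rejected" type="xs:integer" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
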